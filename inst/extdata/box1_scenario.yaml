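# The worked two-condition example: true association P(A|B) = 0.6 versus
# P(A|~B) = 0.2, condition B prevalence 0.1, both conditions under-recorded.
schema_version: 1
p_a_given_b: 0.6
p_a_given_not_b: 0.2
prevalence_b: 0.1
profile_a:
  sensitivity: 0.60
  false_positive_rate: 0.05
profile_b:
  sensitivity: 0.85
  false_positive_rate: 0.03
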