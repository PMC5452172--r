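# Primary parameter sets for the three scenario families, with sensitivity
# suites where bounds are defined (moderation: 0/25/75% energy compensation;
# reformulation: lower 25/10/10/25%, primary 50/25/20/25%, upper 75/40/40/50%).
scenarios:
  - label: moderation_all
    family: moderation
    target: all
    reduction_fraction: 0.5
    compensation_fraction: 0
  - label: moderation_all_suite
    family: moderation
    target: all
    suite: true
  - label: substitution_all
    family: substitution
    target: all
    reduction_fraction: 0.5
  - label: reformulation_all
    family: reformulation
    target: all
  - label: reformulation_all_suite
    family: reformulation
    target: all
    suite: true
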