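# Example override configuration for crcscreen::load_config().
# Any field omitted keeps its base-case value; all rates are fractions.
compliance:
  fit: 0.45
costs:
  colonoscopy: 1500
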