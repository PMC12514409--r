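# Example sweep spec for crcscreen::cea_sweep(): compliance for initial,
# repeated and follow-up screening moved together across its plausible range.
parameter: compliance.all
from: 0.1
to: 1.0
steps: 10
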