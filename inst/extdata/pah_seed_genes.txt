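# Seed set of established PAH risk genes for network proximity triage.
BMPR2
CAV1
TBX4
SOX17
KDR
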