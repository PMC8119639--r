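# Illustrative stand-in for a clinical PAH gene panel (one symbol per line).
# The panel used in any given clinic is a config input; this list contains
# well-established PAH risk genes and is bundled only for examples/tests.
BMPR2
CAV1
TBX4
SOX17
KDR
ACVRL1
ENG
SMAD9
EIF2AK4
GDF2
ATP13A3
AQP1
KCNK3
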