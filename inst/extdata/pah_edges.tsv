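# Illustrative gene-interaction edge list (STRING export surrogate).
# Encodes only relations stated in prose sources: TRAF2 interacts directly
# with CAV1; CAV1 links to the TGF-beta/BMP cluster; TNIP2 and TRAF2
# associate with NF-kB components. Not a faithful copy of any database.
TRAF2	CAV1
CAV1	BMPR2
BMPR2	ACVRL1
BMPR2	SMAD9
TNIP2	NFKB1
TNIP2	TNFAIP3
TRAF2	RELA
NFKB1	RELA
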