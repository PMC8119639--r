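# Example annotation schema: maps VCF INFO keys to internal fields.
# Only keys that differ from the package default need to be listed.
gene: GENE
transcript: TRANSCRIPT
hgvs_c: HGVSC
hgvs_p: HGVSP
consequence: CSQ
cadd: CADD
pop_af:
  gnomad_exomes: AF_GNOMAD_EX
  gnomad_genomes: AF_GNOMAD_GE
  kaviar: AF_KAVIAR
  beacon: AF_BEACON
  bravo: AF_BRAVO
  esp: AF_ESP
  thousand_genomes: AF_1000G3
predictors: DBNSFP
predictor_map:
  D: damaging
  T: tolerated
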