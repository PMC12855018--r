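# Glycolysis -> TCA atom-transition network under a [U-13C6]glucose tracer.
# Lowercase letters are carbon atoms; every letter maps bijectively from
# reactants to products. CO2in feeds pyruvate carboxylase from an unlabelled
# pool; AcCoAin stands for acetyl-CoA from fatty-acid oxidation and
# ketogenic amino acids; GLNin for glutamine (and glucogenic amino acid
# backbones) entering at 2-oxoglutarate.

substrate GLC 0 0 0 0 0 0 1
substrate CO2in 1 0
substrate AcCoAin 1 0 0
substrate GLNin 1 0 0 0 0 0

symmetric SUC FUM
reference V12
free V9 V11 V16
measured CIT SUC FUM MAL

V1:  GLC (abcdef) -> PYR (cba) + PYR (def)
V9:  PYR (abc) + CO2in (d) -> OAA (abcd)
V10: PYR (abc) -> CO2 (a) + AcCoA (bc)
V11: AcCoAin (ab) -> AcCoA (ab)
V12: OAA (abcd) + AcCoA (ef) -> CIT (dcbafe)
V13: CIT (abcdef) -> OGA (abcde) + CO2 (f)
V16: GLNin (abcde) -> GLU (abcde)
V17: GLU (abcde) -> OGA (abcde)
V18: OGA (abcde) -> SUC (bcde) + CO2 (a)
V19: SUC (abcd) -> FUM (abcd)
V20: FUM (abcd) -> MAL (abcd)
V21: MAL (abcd) -> OAA (abcd)
V22: OAA (abcd) -> OAAout (abcd)
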