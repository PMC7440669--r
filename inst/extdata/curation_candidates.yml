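# Candidate futile-cycle members for the iterative curation procedure.
#
# Each entry names the reaction that is capped when its flux exceeds the
# wild-type flux by more than the high-flux threshold, the antagonistic
# partner that closes the cycle, and the co-factor the cycle dissipates.
# The capped member is the one inactive (or lower-flux) in the wild type;
# its partner is the co-factor-consuming reaction that stays functional.

candidates:
  - {cap: FBP,      partner: PFK,     cofactor: ATP,      note: "fructose-bisphosphatase / phosphofructokinase cycle"}
  - {cap: PPS,      partner: PYK,     cofactor: ATP,      note: "PEP synthase / pyruvate kinase cycle"}
  - {cap: PPCK,     partner: PPC,     cofactor: ATP,      note: "PEP carboxykinase / PEP carboxylase cycle"}
  - {cap: GLUN,     partner: GLNS,    cofactor: ATP,      note: "glutaminase / glutamine synthetase cycle"}
  - {cap: GLUSy,    partner: GLUDy,   cofactor: NADPH,    note: "glutamate synthase / glutamate dehydrogenase cycle"}
  - {cap: NADTRHD,  partner: THD2,    cofactor: NADPH,    note: "soluble / membrane transhydrogenase cycle"}
  - {cap: ME1,      partner: MDH,     cofactor: NADH,     note: "malic enzyme bypass of pyruvate kinase"}
  - {cap: ME2,      partner: MDH,     cofactor: NADPH,    note: "NADP malic enzyme bypass of pyruvate kinase"}
  - {cap: FRD7,     partner: SUCDi,   cofactor: quinone,  note: "fumarate reductase / succinate dehydrogenase loop"}
  - {cap: SUCCt2_2, partner: SUCCt3,  cofactor: proton,   note: "succinate transport proton leak"}
  - {cap: FORt2,    partner: FORti,   cofactor: proton,   note: "formate transport proton leak"}
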