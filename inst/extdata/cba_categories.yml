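# Default category rules for the co-factor balance assessment.
#
# Reactions are keyed by their BiGG-style identifiers in the bundled core
# network.  Target reactions are not listed here: they are taken from the
# pathway annotation of each engineered variant.  A reaction listed under a
# waste rule is assigned to the waste category only when its co-factor flux
# score has the stated sign; everything unlisted falls into production
# (positive score) or maintenance (negative score).

biomass:
  - Biomass_Ecoli_core

atp:
  # ATP-hydrolysing ("ATP burning") reactions: maintenance demand and AMP
  # recycling; waste when the ATP score is negative.
  burn: [ATPM, ADK1]
  # Substrate-level phosphorylation coupled to acetate overflow; waste when
  # the ATP score is positive (acetate kinase running towards acetate).
  overflow: [ACKr]

nadph_pool:
  # Dehydrogenases that produce NAD(P)H while releasing CO2; waste when the
  # score is positive.
  co2_coupled: [GND, PDH, AKGDH, ICDHyr]
  # Fermentative NAD(P)H consumers (lactate and ethanol branches); waste when
  # the score is negative.
  fermentation: [LDH_D, ALCD2x, ACALD]

# Oxidative pentose-phosphate dehydrogenases used for the PPP production
# share diagnostic.
ppp_dehydrogenases: [G6PDH2r, GND]
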