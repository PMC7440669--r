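id	name	equation	lower_bound	upper_bound	objective
ACALD	acetaldehyde dehydrogenase (acetylating)	acald_c + coa_c + nad_c <-> accoa_c + h_c + nadh_c	-1000	1000	0
ACKr	acetate kinase	ac_c + atp_c <-> actp_c + adp_c	-1000	1000	0
ACONTa	aconitase (half-reaction A, Citrate hydro-lyase)	cit_c <-> acon_C_c + h2o_c	-1000	1000	0
ACONTb	aconitase (half-reaction B, Isocitrate hydro-lyase)	acon_C_c + h2o_c <-> icit_c	-1000	1000	0
ACt2r	R acetate reversible transport via proton - symport	ac_e + h_e <-> ac_c + h_c	-1000	1000	0
ADK1	adenylate kinase	amp_c + atp_c <-> 2 adp_c	-1000	1000	0
AKGDH	2-Oxogluterate dehydrogenase	akg_c + coa_c + nad_c -> co2_c + nadh_c + succoa_c	0	1000	0
ALCD2x	alcohol dehydrogenase (ethanol)	etoh_c + nad_c <-> acald_c + h_c + nadh_c	-1000	1000	0
ATPM	ATP maintenance requirement	atp_c + h2o_c -> adp_c + h_c + pi_c	8.39	1000	0
ATPS4r	ATP synthase (four protons for one ATP)	adp_c + 4 h_e + pi_c <-> atp_c + h2o_c + 3 h_c	-1000	1000	0
Biomass_Ecoli_core	Biomass Objective Function with GAM	1.496 3pg_c + 3.7478 accoa_c + 59.81 atp_c + 0.361 e4p_c + 0.0709 f6p_c + 0.129 g3p_c + 0.205 g6p_c + 0.2557 gln__L_c + 4.9414 glu__L_c + 59.81 h2o_c + 3.547 nad_c + 13.0279 nadph_c + 1.7867 oaa_c + 0.5191 pep_c + 2.8328 pyr_c + 0.8977 r5p_c -> 59.81 adp_c + 4.1182 akg_c + 3.7478 coa_c + 59.81 h_c + 3.547 nadh_c + 13.0279 nadp_c + 59.81 pi_c	0	1000	1
CO2t	R CO2 transporter via - diffusion	co2_e <-> co2_c	-1000	1000	0
CS	citrate synthase	accoa_c + h2o_c + oaa_c -> cit_c + coa_c + h_c	0	1000	0
CYTBD	cytochrome oxidase bd (ubiquinol-8: 2 protons)	2 h_c + 0.5 o2_c + q8h2_c -> h2o_c + 2 h_e + q8_c	0	1000	0
ENO	enolase	2pg_c <-> h2o_c + pep_c	-1000	1000	0
ETOHt2r	ETOHt2r	etoh_e + h_e <-> etoh_c + h_c	-1000	1000	0
EX_ac_e	Acetate exchange	ac_e -> 	0	1000	0
EX_co2_e	CO2 exchange	co2_e <-> 	-1000	1000	0
EX_etoh_e	Ethanol exchange	etoh_e -> 	0	1000	0
EX_for_e	Formate exchange	for_e -> 	0	1000	0
EX_glc__D_e	D-Glucose exchange	glc__D_e <-> 	-10	1000	0
EX_h2o_e	H2O exchange	h2o_e <-> 	-1000	1000	0
EX_h_e	H+ exchange	h_e <-> 	-1000	1000	0
EX_nh4_e	Ammonia exchange	nh4_e <-> 	-1000	1000	0
EX_o2_e	O2 exchange	o2_e <-> 	-1000	1000	0
EX_pi_e	Phosphate exchange	pi_e <-> 	-1000	1000	0
EX_succ_e	Succinate exchange	succ_e -> 	0	1000	0
FBA	fructose-bisphosphate aldolase	fdp_c <-> dhap_c + g3p_c	-1000	1000	0
FBP	fructose-bisphosphatase	fdp_c + h2o_c -> f6p_c + pi_c	0	1000	0
FORt2	formate transport in via proton symport	for_e + h_e -> for_c + h_c	0	1000	0
FORti	formate transport via diffusion	for_c -> for_e	0	1000	0
FRD7	fumarate reductase	fum_c + q8h2_c -> q8_c + succ_c	0	1000	0
FUM	fumarase	fum_c + h2o_c <-> mal__L_c	-1000	1000	0
G6PDH2r	glucose 6-phosphate dehydrogenase	g6p_c + nadp_c <-> 6pgl_c + h_c + nadph_c	-1000	1000	0
GAPD	glyceraldehyde-3-phosphate dehydrogenase	g3p_c + nad_c + pi_c <-> 13dpg_c + h_c + nadh_c	-1000	1000	0
GLCpts	D-glucose transport via PEP:Pyr PTS	glc__D_e + pep_c -> g6p_c + pyr_c	0	1000	0
GLNS	glutamine synthetase	atp_c + glu__L_c + nh4_c -> adp_c + gln__L_c + h_c + pi_c	0	1000	0
GLUDy	glutamate dehydrogenase (NADP)	glu__L_c + h2o_c + nadp_c <-> akg_c + h_c + nadph_c + nh4_c	-1000	1000	0
GLUN	glutaminase	gln__L_c + h2o_c -> glu__L_c + nh4_c	0	1000	0
GLUSy	glutamate synthase (NADPH)	akg_c + gln__L_c + h_c + nadph_c -> 2 glu__L_c + nadp_c	0	1000	0
GND	phosphogluconate dehydrogenase	6pgc_c + nadp_c -> co2_c + nadph_c + ru5p__D_c	0	1000	0
H2Ot	R H2O transport via - diffusion	h2o_e <-> h2o_c	-1000	1000	0
ICDHyr	isocitrate dehydrogenase (NADP)	icit_c + nadp_c <-> akg_c + co2_c + nadph_c	-1000	1000	0
ICL	Isocitrate lyase	icit_c -> glx_c + succ_c	0	1000	0
LDH_D	D-lactate dehydrogenase	lac__D_c + nad_c <-> h_c + nadh_c + pyr_c	-1000	1000	0
MALS	malate synthase	accoa_c + glx_c + h2o_c -> coa_c + h_c + mal__L_c	0	1000	0
MDH	malate dehydrogenase	mal__L_c + nad_c <-> h_c + nadh_c + oaa_c	-1000	1000	0
ME1	malic enzyme (NAD)	mal__L_c + nad_c -> co2_c + nadh_c + pyr_c	0	1000	0
ME2	malic enzyme (NADP)	mal__L_c + nadp_c -> co2_c + nadph_c + pyr_c	0	1000	0
NADH16	NADH dehydrogenase (ubiquinone-8 & 3 protons)	4 h_c + nadh_c + q8_c -> 3 h_e + nad_c + q8h2_c	0	1000	0
NADTRHD	NAD transhydrogenase	nad_c + nadph_c -> nadh_c + nadp_c	0	1000	0
NH4t	R ammonia reversible - transport	nh4_e <-> nh4_c	-1000	1000	0
O2t	R o2 - transport-diffusion	o2_e <-> o2_c	-1000	1000	0
PDH	pyruvate dehydrogenase	coa_c + nad_c + pyr_c -> accoa_c + co2_c + nadh_c	0	1000	0
PFK	phosphofructokinase	atp_c + f6p_c -> adp_c + fdp_c + h_c	0	1000	0
PFL	pyruvate formate lyase	coa_c + pyr_c -> accoa_c + for_c	0	1000	0
PGI	glucose-6-phosphate isomerase	g6p_c <-> f6p_c	-1000	1000	0
PGK	phosphoglycerate kinase	3pg_c + atp_c <-> 13dpg_c + adp_c	-1000	1000	0
PGL	6-phosphogluconolactonase	6pgl_c + h2o_c -> 6pgc_c + h_c	0	1000	0
PGM	phosphoglycerate mutase	2pg_c <-> 3pg_c	-1000	1000	0
PIt2r	R phosphate reversible transport via - symport	h_e + pi_e <-> h_c + pi_c	-1000	1000	0
PPC	phosphoenolpyruvate carboxylase	co2_c + h2o_c + pep_c -> h_c + oaa_c + pi_c	0	1000	0
PPCK	phosphoenolpyruvate carboxykinase	atp_c + oaa_c -> adp_c + co2_c + pep_c	0	1000	0
PPS	phosphoenolpyruvate synthase	atp_c + h2o_c + pyr_c -> amp_c + 2 h_c + pep_c + pi_c	0	1000	0
PTAr	phosphotransacetylase	accoa_c + pi_c <-> actp_c + coa_c	-1000	1000	0
PYK	pyruvate kinase	adp_c + h_c + pep_c -> atp_c + pyr_c	0	1000	0
RPE	ribulose 5-phosphate 3-epimerase	ru5p__D_c <-> xu5p__D_c	-1000	1000	0
RPI	ribose-5-phosphate isomerase	r5p_c <-> ru5p__D_c	-1000	1000	0
SUCCt2_2	R succinate transport via proton symport-2 - H	2 h_e + succ_e -> 2 h_c + succ_c	0	1000	0
SUCCt3	succinate transport out via proton antiport	h_e + succ_c -> h_c + succ_e	0	1000	0
SUCDi	succinate dehydrogenase (irreversible)	q8_c + succ_c -> fum_c + q8h2_c	0	1000	0
SUCOAS	succinyl-CoA synthetase (ADP-forming)	atp_c + coa_c + succ_c <-> adp_c + pi_c + succoa_c	-1000	1000	0
TALA	transaldolase	g3p_c + s7p_c <-> e4p_c + f6p_c	-1000	1000	0
THD2	R NAD - P-transhydrogenase	2 h_e + nadh_c + nadp_c -> 2 h_c + nad_c + nadph_c	0	1000	0
TKT1	transketolase	r5p_c + xu5p__D_c <-> g3p_c + s7p_c	-1000	1000	0
TKT2	transketolase	e4p_c + xu5p__D_c <-> f6p_c + g3p_c	-1000	1000	0
TPI	triose-phosphate isomerase	dhap_c <-> g3p_c	-1000	1000	0
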