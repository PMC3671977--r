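# Published classification of the 35 seminal-plasma proteins, transcribed as
# a constraint table. present_<G> = number of the group's replicates in which
# the protein was identified (NN has 5 replicates, NA 4, OA 2, ON 1).
# class_<G>: significant / low / absent, the effective per-group abundance
# class after applying the rule set (sc_threshold 10, presence quota
# floor-half, significance dominant at the boundary). dep_<G>: expected
# differential-expression call vs the NN baseline (up / down / none / any;
# "any" = a call must be present but its direction is not constrained).
# printed_dep / printed_sig / printed_low preserve the published wording.
# relaxation marks the two cells where the printed annotation is
# unsatisfiable under the rule set and the encoded constraint deliberately
# deviates (see package docs).
accession	name	present_NN	present_NA	present_OA	present_ON	class_NN	class_NA	class_OA	class_ON	dep_NA	dep_OA	dep_ON	global_low	printed_dep	printed_sig	printed_low	relaxation	note
4505821	prolactin-induced protein	5	4	2	1	significant	significant	significant	significant	none	none	none	0		NN, NA, OA, ON
4506885	semenogelin II precursor	5	4	2	1	significant	significant	significant	significant	none	none	none	0		NN, NA, OA, ON
4502027	albumin preproprotein	5	4	2	1	significant	significant	significant	significant	none	none	none	0		NN, NA, OA, ON
54607120	lactotransferrin	5	4	2	1	significant	significant	significant	significant	none	none	none	0		NN, NA, OA, ON
5453678	epididymal secretory protein E1 precursor	5	4	2	1	significant	significant	significant	significant	none	none	none	0		NN, NA, OA, ON
221316614	extracellular matrix protein 1 isoform 1 precursor	5	4	2	1	significant	significant	significant	significant	none	none	none	0		NN, NA, OA, ON
11386147	prosaposin isoform a preproprotein	5	4	2	1	significant	significant	significant	significant	none	none	none	0		NN, NA, OA, ON
4503143	cathepsin D preproprotein	5	4	2	1	significant	significant	significant	significant	none	none	none	0		NN, NA, OA, ON
4502173	prostate specific antigen isoform 1 preproprotein	5	4	2	1	significant	significant	significant	significant	none	up	none	0	up:OA	NN, NA, OA, ON
4502337	zinc alpha-2-glycoprotein 1	5	4	2	1	significant	significant	significant	significant	none	none	up	0	up:ON	NN, NA, OA, ON
42716297	clusterin isoform 1	5	4	2	1	significant	significant	significant	low	none	none	down	0	down:ON	NN, NA, OA	Low in ON
151301154	mucin 6, gastric	4	4	2	1	significant	significant	significant	significant	down	none	none	0	down:NA	NN, NA, OA, ON
4503109	cystatin S precursor	4	4	2	1	significant	significant	significant	low	down	down	down	0	down:NA,OA,ON	NN, NA, OA	Low in ON
5031863	galectin 3 binding protein	5	3	2	1	significant	significant	low	low	none	down	down	0	down:OA,ON	NN, NA	Low in OA and ON
38049014	semenogelin I isoform b preproprotein	3	4	2	1	significant	significant	significant	significant	none	up	none	0	up:OA	NN, NA, OA, ON
6382064	prostatic acid phosphatase precursor	4	3	2	1	significant	significant	significant	low	down	none	down	0	down:NA,ON	NN, NA, OA	Low in ON
4503107	cystatin C precursor	4	3	1	1	significant	significant	significant	significant	none	down	none	0	down:OA	NN, NA, OA, ON
4507509	tissue inhibitor of metalloproteinase 1 precursor	3	3	1	1	significant	significant	significant	significant	none	none	up	0	up:ON	NN, NA, OA, ON
4757826	beta 2 microglobulin precursor	3	3	1	1	significant	significant	low	significant	none	down	up	0	down:OA;up:ON	NN, NA, ON	Low in OA
31543380	DJ-1 protein	2	3	0	1	significant	significant	absent	significant	up	none	up	0	up:NA,ON	NN, NA, ON
56676397	ankyrin repeat domain 11	0	1	2	1	absent	low	significant	low	none	any	any	0	down:OA,ON	OA	Low in NA and ON	direction_unconstrained	absent in baseline NN; printed down-calls unreachable, calls kept with free direction
167857790	orosomucoid 1 precursor	2	1	0	0	significant	low	absent	absent	down	none	none	0	down:NA	NN	Low in NA		printed sample total 2 conflicts with cells NN(2)+NA(1)
50363217	serine proteinase inhibitor, clade A, member 1	3	3	1	1	low	significant	low	significant	up	down	up	0	up:NA,ON;down:OA	NA, OA, ON		oa_significant_to_low	printed OA significance incompatible with down-in-OA plus non-significant NN
4557871	transferrin	2	3	1	0	low	low	low	absent	up	up	none	1	up:NA,OA	NONE	Low abundant
4507065	secretory leukocyte peptidase inhibitor precursor	1	3	1	0	low	low	low	absent	up	up	none	1	up:NA,OA	NONE	Low abundant
4506713	ubiquitin and ribosomal protein S27a precursor	2	1	1	0	low	low	low	absent	down	down	none	1	down:NA,OA	NONE	Low abundant
104487006	protein tyrosine phosphatase, receptor type, sigma isoform 1 precursor	1	2	0	1	low	low	absent	low	up	none	up	1	up:NA,ON	NONE	Low abundant
25121982	acidic epididymal glycoprotein-like 1 isoform 1 precursor	2	1	0	0	low	low	absent	absent	down	none	none	1	down:NA	NONE	Low abundant
32171249	prostaglandin H2 D-isomerase	2	2	1	0	low	low	low	absent	none	none	none	1		NONE	Low abundant
4503139	cathepsin B preproprotein	3	3	0	0	low	low	absent	absent	none	none	none	1		NONE	Low abundant
19923082	expressed in prostate and testis	2	1	1	0	low	low	low	absent	none	none	none	1		NONE	Low abundant
4505529	orosomucoid 2	1	0	0	0	low	absent	absent	absent	none	none	none	1		NONE	Low abundant
110735433	CD177 molecule	0	1	1	1	absent	low	low	low	none	none	none	1		NONE	Low abundant		printed ON cell reads "(1n with (1))", presumed ON(1)
4503009	carboxypeptidase E preproprotein	3	3	2	1	significant	significant	low	low	none	none	none	0		NN, NA	Low in OA and ON
47132551	fibronectin 1 isoform 2 preproprotein	4	4	1	1	significant	significant	significant	low	none	none	none	0		NN, NA, OA	Low in ON
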