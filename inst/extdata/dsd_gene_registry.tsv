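symbol	locus	omim	category	inheritance	lof_mechanism	coverage20x	associated_dsd
BMP15	Xp11.22	300247	gonadal_development	AD	TRUE	95	46,XX DSD ovarian dysgenesis
CBX2	17q25.3	602770	gonadal_development	AR	TRUE	96	46,XY DSD CGD
DHH	12q13.12	605423	gonadal_development	AR,AD	TRUE	99	46,XY PGD or CGD
DMRT1	9p24.3	602424	gonadal_development	AD	TRUE	98	46,XY DSD (deletion)
DMRT2	9p24.3	604935	gonadal_development	AD	TRUE	99	46,XY DSD (deletion)
FOXL2	3q22.3	608996	gonadal_development	AD	TRUE	94	POI alone or with blepharophimosis-ptosis-epicanthus inversus
GATA4	8p23.1	600576	gonadal_development	AD	TRUE	91	46,XY DSD
NR0B1	Xp21.2	300473	gonadal_development	XL_dup,XL	FALSE	100	46,XY GD gain of function (dup); 46,XX CAH with HH
NR5A1	9q33.3	184757	gonadal_development	AD	TRUE	100	46,XY DSD (various); 46,XX POI
MAP3K1	5q11.2	600982	gonadal_development	AD	TRUE	99	46,XY GD
RSPO1	1p34.3	609595	gonadal_development	AR	TRUE	94	46,XX OT DSD with palmoplantar hyperkeratosis
SOX3	Xq27.1	313430	gonadal_development	XL_dup	FALSE	92	46,XX T or OT DSD gain of function (dup)
SOX9	17q24.3	608106	gonadal_development	AD,AD_dup	TRUE	95	46,XY GD and campomelic dysplasia; 46,XX T DSD (dup)
SRY	Yp11.2	480000	gonadal_development	AD	TRUE	58	46,XX T DSD (translocation); 46,XY ovarian DSD
TSPYL1	6q22.1	604714	gonadal_development	AR	TRUE	99	46,XY DSD with sudden infant death syndrome
WNT4	1p36.12	603490	gonadal_development	AD_dup,AR,AD	TRUE	99	46,XY ovo/OT DSD or CGD (dup); 46,XX T DSD; MRKH
WT1	11p13	607102	gonadal_development	AD	TRUE	99	Frasier syndrome and Denys-Drash
ZFPM2	8q23.1	603693	gonadal_development	AD	TRUE	99	46,XY GD
AKR1C2	10p15.1	600450	androgen_synthesis_action	AR	TRUE	82	46,XY DSD
AKR1C4	10p15.1	600451	androgen_synthesis_action	AR	TRUE	99	46,XY DSD
AMH	19p13.3	600957	androgen_synthesis_action	AR	TRUE	94	PMDS
AMHR2	12q13.13	600956	androgen_synthesis_action	AR	TRUE	100	PMDS
AR	Xq12	313700	androgen_synthesis_action	XL	TRUE	97	46,XY DSD; complete/partial AIS; isolated hypospadias
ARX	Xp21.3	300215	androgen_synthesis_action	XL	TRUE	90	X-linked lissencephaly with ambiguous genitalia
ATRX	Xq21.1	300032	androgen_synthesis_action	XL	TRUE	99	46,XY DSD with alpha-thalassemia X-linked intellectual disability
CDKN1C	11p15.4	600856	androgen_synthesis_action	AD	TRUE	61	Genital anomalies with Beckwith-Wiedemann and IMAGE syndromes
CYB5A	18q22.3	613218	androgen_synthesis_action	AR	TRUE	99	46,XY DSD
CYP11A1	15q24.1	118485	androgen_synthesis_action	AR,AD	TRUE	100	46,XY sex reversal with adrenal insufficiency; hypospadias
CYP11B1	8q24.3	610613	androgen_synthesis_action	AR	TRUE	86	46,XX DSD; CAH (11-beta-hydroxylase deficiency)
CYP17A1	10q24.32	609300	androgen_synthesis_action	AR	TRUE	100	46,XY DSD; 17,20-lyase deficiency CAH
CYP19A1	15q21.2	107910	androgen_synthesis_action	AR	TRUE	100	46,XY DSD; aromatase deficiency
CYP21A2	6p21.33	613815	androgen_synthesis_action	AR	TRUE	6	46,XX DSD virilization; 21-hydroxylase-deficient CAH
FGFR2	10q26.13	176943	androgen_synthesis_action	AD	TRUE	99	46,XY GD with craniosynostosis; Apert syndrome
HSD17B3	9q22.32	605573	androgen_synthesis_action	AR	TRUE	100	46,XY DSD; 17-beta-hydroxysteroid dehydrogenase III deficiency
HSD17B4	5q23.1	233400	androgen_synthesis_action	AR	TRUE	98	Perrault syndrome (ovarian dysgenesis in 46,XX)
HSD3B2	1p12	613890	androgen_synthesis_action	AR,AD	TRUE	99	46,XY and 46,XX DSD; 3-beta-HSD-deficient CAH; hypospadias
LHCGR	2p16.3	152790	androgen_synthesis_action	AR,AD	TRUE	100	46,XY DSD Leydig cell hypoplasia; male precocious puberty
NR3C1	5q31.3	138040	androgen_synthesis_action	AD	TRUE	96	46,XX hyperandrogenism
POR	7q11.23	124015	androgen_synthesis_action	AR	TRUE	95	Cytochrome P450 oxidoreductase deficiency
SRD5A2	2p23.1	607306	androgen_synthesis_action	AR,AD	TRUE	100	46,XY DSD; steroid 5-alpha-reductase deficiency; hypospadias
STAR	8p11.23	600617	androgen_synthesis_action	AR	TRUE	100	46,XY DSD; cholesterol desmolase-deficient CAH
BBS9	7p14.3	615986	central_hypogonadism	AR	TRUE	96	Bardet-Biedl syndrome
CHD7	8q12.2	608892	central_hypogonadism	AD	TRUE	99	CHH or KS; CHARGE syndrome
FGF8	10q24.32	612702	central_hypogonadism	AD	TRUE	88	CHH or KS
FGFR1	8p11.23	147950	central_hypogonadism	AD	TRUE	100	CHH or KS
FSHB	11p14.1	136530	central_hypogonadism	AD	TRUE	98	CHH
FSHR	2p16.3	136435	central_hypogonadism	AR	TRUE	100	46,XX ovarian dysgenesis
GNRH1	8p21.2	152760	central_hypogonadism	AR	TRUE	100	CHH
GNRHR	4q13.2	138850	central_hypogonadism	AR	TRUE	100	CHH
HESX1	3p14.3	601802	central_hypogonadism	AD	TRUE	98	KS or CPHD
KAL1	Xp22.31	300836	central_hypogonadism	XL	TRUE	97	CHH or KS
KISS1R	19p13.3	604161	central_hypogonadism	AD	TRUE	96	CHH or KS
LEP	7q32.1	164160	central_hypogonadism	AR	TRUE	99	CHH with obesity
LHX3	9q34.3	600577	central_hypogonadism	AR	TRUE	89	CPHD
PROK2	3p13	607002	central_hypogonadism	AD	TRUE	99	CHH or KS
PROKR2	20p12.3	607123	central_hypogonadism	AD	TRUE	100	CHH or KS
PROP1	5q35.3	601538	central_hypogonadism	AR	TRUE	98	CPHD
TAC3	12q13.3	162330	central_hypogonadism	AR	TRUE	98	CHH
WDR11	10q26.12	606417	central_hypogonadism	AD	TRUE	93	CHH or KS
ATF3	1q32.3	603148	other	AD	TRUE	97	46,XY isolated hypospadias
HOXA13	7p15.2	142959	other	AD	TRUE	93	Hand-foot-uterus syndrome; MRKH in 46,XX; Guttmacher syndrome
INSL3	19p13.11	146738	other	AD	TRUE	99	Cryptorchidism
MAMLD1	Xq28	300120	other	XL	TRUE	100	Hypospadias
RXFP2	13q13.1	606655	other	AD	TRUE	96	Cryptorchidism
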