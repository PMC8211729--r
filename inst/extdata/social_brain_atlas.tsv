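region_id	x	y	z	network	label
AI_L	-34	19	0	intermediate	Left anterior insula
AI_R	38	18	-3	intermediate	Right anterior insula
AM_L	-21	-4	-18	limbic	Left amygdala
AM_R	23	-3	-18	limbic	Right amygdala
aMCC	1	25	30	intermediate	Anterior mid-cingulate cortex
CB_L	-21	-66	-35	intermediate	Left cerebellum
CB_R	28	-70	-30	intermediate	Right cerebellum
dmPFC	-4	53	31	higher-associative	Dorsomedial prefrontal cortex
FG_L	-42	-62	-16	visual-sensory	Left fusiform gyrus
FG_R	43	-57	-19	visual-sensory	Right fusiform gyrus
FP	1	58	10	higher-associative	Medial frontal pole
HC_L	-24	-18	-17	limbic	Left hippocampus
HC_R	25	-19	-15	limbic	Right hippocampus
IFG_L	-45	27	-3	intermediate	Left inferior frontal gyrus
IFG_R	48	24	2	intermediate	Right inferior frontal gyrus
MTG_L	-56	-14	-13	higher-associative	Left middle temporal gyrus
MTG_R	56	-10	-17	higher-associative	Right middle temporal gyrus
MT/V5_L	-50	-66	5	visual-sensory	Left middle temporal V5 area
MT/V5_R	50	-66	6	visual-sensory	Right middle temporal V5 area
NAC_L	-13	11	-8	limbic	Left nucleus accumbens
NAC_R	11	10	-7	limbic	Right nucleus accumbens
PCC	-1	-54	23	higher-associative	Posterior cingulate cortex
pMCC	-3	-29	32	higher-associative	Posterior mid-cingulate cortex
Prec	-1	-59	41	higher-associative	Precuneus
pSTS_L	-56	-39	2	visual-sensory	Left posterior superior temporal sulcus
pSTS_R	54	-39	0	visual-sensory	Right posterior superior temporal sulcus
rACC	-3	41	4	limbic	Rostral anterior cingulate cortex
SMA_L	-41	6	45	intermediate	Left supplementary motor area
SMA_R	48	6	35	intermediate	Right supplementary motor area
SMG_L	-41	-41	42	intermediate	Left supramarginal gyrus
SMG_R	54	-30	38	intermediate	Right supramarginal gyrus
TP_L	-48	8	-36	higher-associative	Left temporal pole
TP_R	53	7	-26	higher-associative	Right temporal pole
TPJ_L	-49	-61	27	higher-associative	Left temporo-parietal junction
TPJ_R	54	-55	20	higher-associative	Right temporo-parietal junction
vmPFC	2	45	-15	limbic	Ventromedial prefrontal cortex
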