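roi	label	hemisphere	lobe	cluster
Banks of superior temporal sulcus	BK_L	L	Temporal	temporocentral
Banks of superior temporal sulcus	BK_R	R	Temporal	temporocentral
Caudal anterior cingulate	cAC_L	L	Frontal	frontal
Caudal anterior cingulate	cAC_R	R	Frontal	frontal
Caudal middle frontal	cMF_L	L	Frontal	frontal
Caudal middle frontal	cMF_R	R	Frontal	frontal
Cuneus	CU_L	L	Occipital	posterior
Cuneus	CU_R	R	Occipital	posterior
Entorhinal	EN_L	L	Temporal	temporocentral
Entorhinal	EN_R	R	Temporal	temporocentral
Frontal pole	FP_L	L	Frontal	frontal
Frontal pole	FP_R	R	Frontal	frontal
Fusiform	FU_L	L	Temporal	temporocentral
Fusiform	FU_R	R	Temporal	temporocentral
Insula	IN_L	L	Parietal	temporocentral
Insula	IN_R	R	Parietal	temporocentral
Inferior parietal	IP_L	L	Parietal	posterior
Inferior parietal	IP_R	R	Parietal	posterior
Isthmus cingulate	IST_L	L	Parietal	temporocentral
Isthmus cingulate	IST_R	R	Parietal	temporocentral
Inferior temporal	IT_L	L	Temporal	temporocentral
Inferior temporal	IT_R	R	Temporal	temporocentral
Lingual	LG_L	L	Occipital	posterior
Lingual	LG_R	R	Occipital	posterior
Lateral occipital	LO_L	L	Occipital	posterior
Lateral occipital	LO_R	R	Occipital	posterior
Lateral orbitofrontal	lOF_L	L	Frontal	frontal
Lateral orbitofrontal	lOF_R	R	Frontal	frontal
Medial orbitofrontal	mOF_L	L	Frontal	frontal
Medial orbitofrontal	mOF_R	R	Frontal	frontal
Middle temporal	MT_L	L	Temporal	temporocentral
Middle temporal	MT_R	R	Temporal	temporocentral
Paracentral	PAC_L	L	Frontal	temporocentral
Paracentral	PAC_R	R	Frontal	temporocentral
Posterior cingulate	PCG_L	L	Parietal	posterior
Posterior cingulate	PCG_R	R	Parietal	posterior
Pericalcarine	PCL_L	L	Occipital	posterior
Pericalcarine	PCL_R	R	Occipital	posterior
Precuneus	PCU_L	L	Parietal	posterior
Precuneus	PCU_R	R	Parietal	posterior
Parahippocampal	PH_L	L	Temporal	temporocentral
Parahippocampal	PH_R	R	Temporal	temporocentral
Postcentral	POC_L	L	Parietal	temporocentral
Postcentral	POC_R	R	Parietal	temporocentral
Pars opercularis	pOP_L	L	Frontal	frontal
Pars opercularis	pOP_R	R	Frontal	frontal
Pars orbitalis	pOR_L	L	Frontal	frontal
Pars orbitalis	pOR_R	R	Frontal	frontal
Precentral	PRC_L	L	Frontal	temporocentral
Precentral	PRC_R	R	Frontal	temporocentral
Pars triangularis	pTR_L	L	Frontal	frontal
Pars triangularis	pTR_R	R	Frontal	frontal
Rostral anterior cingulate	rAC_L	L	Frontal	frontal
Rostral anterior cingulate	rAC_R	R	Frontal	frontal
Rostral middle frontal	rMF_L	L	Frontal	frontal
Rostral middle frontal	rMF_R	R	Frontal	frontal
Superior frontal	SF_L	L	Frontal	frontal
Superior frontal	SF_R	R	Frontal	frontal
Supramarginal	SMG_L	L	Parietal	posterior
Supramarginal	SMG_R	R	Parietal	posterior
Superior parietal	SP_L	L	Parietal	posterior
Superior parietal	SP_R	R	Parietal	posterior
Superior temporal	ST_L	L	Temporal	temporocentral
Superior temporal	ST_R	R	Temporal	temporocentral
Temporal pole	TP_L	L	Temporal	temporocentral
Temporal pole	TP_R	R	Temporal	temporocentral
Transverse temporal	TT_L	L	Temporal	temporocentral
Transverse temporal	TT_R	R	Temporal	temporocentral
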