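region_name	hemisphere	structural_index	functional_index	tissue_class	volume_mm3
Accumbens	right	1	1	GM	12
Amygdala	right	2	2	GM	18
Anterior commissure and bed nucleus	right	3		WM	6.5
Caudate putamen and globus pallidus	right	4	3	GM	48
Corpus callosum	right	5		WM	22
Auditory cortex	right	6	4	GM	26
Cingulate cortex	right	7	5	GM	24
Entorhinal cortex	right	8	6	GM	21
Frontal association cortex	right	9	7	GM	9.5
Insular cortex	right	10	8	GM	17
Medial prefrontal cortex	right	11	9	GM	15
Motor cortex	right	12	10	GM	52
Orbitofrontal cortex	right	13	11	GM	19
Parietal association and somatosensory cortex	right	14	12	GM	60
Piriform cortex	right	15	13	GM	23
Retrosplenial cortex	right	16	14	GM	20
Temporal association cortex	right	17	15	GM	14
Visual cortex	right	18	16	GM	34
Septum and diagonal band	right	19	17	GM	16
Hippocampus anterodorsal	right	20	18	GM	17.5
Hippocampus posterior	right	21	19	GM	19.5
Hippocampus subiculum	right	22	20	GM	11
Hippocampus ventral and hypothalamus lateral	right	23	21	GM	25
Hypothalamus medial and ventral tegmental area	right	24	22	GM	22.5
Internal capsule	right	25		WM	8
Interstitial nucleus of the posterior limb of the anterior commissure, olfactory nuclei, substantia innominata, and ventral pallidum	right	26	23	GM	27
Medial geniculate	right	27		WM	4.5
Mesencephalic region	right	28		WM	30
Olfactory tubercle	right	29	24	GM	13
Periaqueductal gray	right	30		WM	10.5
Pons	right	31		WM	28
Raphe	right	32		WM	5.5
Substantia nigra	right	33		WM	7.5
Superior colliculus	right	34	25	GM	16.5
Thalamus dorsolateral	right	35	26	GM	21.5
Thalamus midline dorsal and ventromedial	right	36	27	GM	24.5
Zona incerta	right	37		WM	6
Fimbria	right	38		WM	9
Accumbens	left	39	28	GM	12
Amygdala	left	40	29	GM	18
Anterior commissure and bed nucleus	left	41		WM	6.5
Caudate putamen and globus pallidus	left	42	30	GM	48
Corpus callosum	left	43		WM	22
Auditory cortex	left	44	31	GM	26
Cingulate cortex	left	45	32	GM	24
Entorhinal cortex	left	46	33	GM	21
Frontal association cortex	left	47	34	GM	9.5
Insular cortex	left	48	35	GM	17
Medial prefrontal cortex	left	49	36	GM	15
Motor cortex	left	50	37	GM	52
Orbitofrontal cortex	left	51	38	GM	19
Parietal association and somatosensory cortex	left	52	39	GM	60
Piriform cortex	left	53	40	GM	23
Retrosplenial cortex	left	54	41	GM	20
Temporal association cortex	left	55	42	GM	14
Visual cortex	left	56	43	GM	34
Septum and diagonal band	left	57	44	GM	16
Hippocampus anterodorsal	left	58	45	GM	17.5
Hippocampus posterior	left	59	46	GM	19.5
Hippocampus subiculum	left	60	47	GM	11
Hippocampus ventral and hypothalamus lateral	left	61	48	GM	25
Hypothalamus medial and ventral tegmental area	left	62	49	GM	22.5
Internal capsule	left	63		WM	8
Interstitial nucleus of the posterior limb of the anterior commissure, olfactory nuclei, substantia innominata, and ventral pallidum	left	64	50	GM	27
Medial geniculate	left	65		WM	4.5
Mesencephalic region	left	66		WM	30
Olfactory tubercle	left	67	51	GM	13
Periaqueductal gray	left	68		WM	10.5
Pons	left	69		WM	28
Raphe	left	70		WM	5.5
Substantia nigra	left	71		WM	7.5
Superior colliculus	left	72	52	GM	16.5
Thalamus dorsolateral	left	73	53	GM	21.5
Thalamus midline dorsal and ventromedial	left	74	54	GM	24.5
Zona incerta	left	75		WM	6
Fimbria	left	76		WM	9
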