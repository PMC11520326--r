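name,group,volume_mm3,suvr_wt,suvr_ko
Locus coeruleus,catecholaminergic,2,1.164,1.164
Thalamus,catecholaminergic,25,1.196,1.196
Prelimbic area,catecholaminergic,6,1.320,1.206
Substantia nigra,catecholaminergic,3.5,0.982,0.982
Striatum,catecholaminergic,40,1.176,1.116
Hypoglossal nucleus,dysarthria,2.5,1.056,1.056
Solitary nucleus,dysarthria,3,1.117,1.117
Nucleus ambiguus,dysarthria,1.5,0.890,0.923
Periaqueductal gray,dysarthria,4,1.216,1.216
Globus pallidus,PDRP,5,1.159,1.159
Pons,PDRP,18,1.010,1.010
Secondary motor area,PDRP,10,1.016,1.016
Parietal assoc. cortex medial,PDRP,4.5,0.870,0.870
Caudate putamen,PDRP,30,1.187,1.187
Cerebellum,PDRP,55,0.914,0.914
Primary motor area,PDRP,14,0.976,0.976
Parietal assoc. cortex posterior,PDRP,6,0.812,0.856
Primary visual area,PDRP,8,0.883,0.883
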