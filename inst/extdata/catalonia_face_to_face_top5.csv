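label,n_2019,n_2020
"Diseases of the blood and blood-forming organs and disorders affecting the immune mechanism (D50-D89)",19912,7285
"Mental, behavioral, and neurodevelopmental disorders (F01-F99)",89415,39196
"Diseases of the ear and mastoid process (H60-H95)",45515,22700
"Diseases of the digestive system (K00-K95)",67589,28439
"Congenital malformations, congenital deformities, and congenital chromosomal anomalies (Q00-Q99)",4668,2439
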