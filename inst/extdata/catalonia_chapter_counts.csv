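label,n_2019,n_2020
"Factors influencing health status and contact with health services (Z00-Z99)",186604,296764
"Endocrine, nutritional, and metabolic diseases (E00-E89)",261076,202933
"Diseases of the circulatory system (I00-I99)",252555,187701
"Diseases of the musculoskeletal system and connective tissue (M00-M99)",224901,180912
"Signs, symptoms, and abnormal test results not elsewhere classified (R00-R99)",200711,184410
"Diseases of the respiratory system (J00-J99)",176405,120669
"Mental, behavioral, and neurodevelopmental disorders (F01-F99)",109203,105506
"Diseases of the genitourinary system (N00-N99)",96692,85950
"Injuries, poisonings, and other consequences of external causes (S00-T88)",105135,76910
"Diseases of the skin and subcutaneous tissue (L00-L99)",89119,75640
"Certain infectious and parasitic diseases (A00-B99)",52220,99779
"Diseases of the digestive system (K00-K95)",78968,64825
"Neoplasms (C00-D49)",55201,47709
"Diseases of the ear and mastoid process (H60-H95)",47699,33796
"Diseases of the nervous system (G00-G99)",38057,34093
"Diseases of the eye and adnexa (H00-H59)",36837,24973
"Diseases of the blood and blood-forming organs and disorders affecting the immune mechanism (D50-D89)",25305,20246
"External causes of morbidity (V00-Y99)",12481,11178
"Congenital malformations, congenital deformities, and congenital chromosomal anomalies (Q00-Q99)",5493,4541
"Pregnancy, childbirth, and puerperium (O00-O9A)",3788,3235
"Certain conditions originating in the perinatal period (P00-P96)",991,763
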