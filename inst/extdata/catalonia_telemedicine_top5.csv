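label,n_2019,n_2020
"Factors influencing health status and contact with health services (Z00-Z99)",32146,167318
"Signs, symptoms, and abnormal test results not elsewhere classified (R00-R99)",27092,101122
"Diseases of the musculoskeletal system and connective tissue (M00-M99)",27328,99965
"Endocrine, nutritional, and metabolic diseases (E00-E89)",44155,113508
"Certain infectious and parasitic diseases (A00-B99)",4670,167318
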