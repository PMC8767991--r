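characteristic,family,n_2019,n_2020
total_patients,patients,287936,287965
total_visits,visits,1421779,1402406
face_to_face,modality,1212800,633858
telemedicine,modality,208979,768548
general_medicine,specialty,859153,822433
nursing,specialty,427959,473051
pediatrics,specialty,134667,106922
early_childhood,age_group,95098,76460
childhood,age_group,57436,52101
adolescence,age_group,55768,61693
youth,age_group,55943,69287
adulthood,age_group,475366,514327
older_adult,age_group,682168,628538
total_codes,codes,2079680,1912342
male,sex,641602,627806
female,sex,780074,774486
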