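study_id,n,n_female,n_male,mean_age,sd_age,scale,space,contrast_id,x,y,z,sign
study_01,30,13,17,23.57,3.70,NEO-PI-R,MNI,,,,,
study_02,52,29,23,25.0,5.1,NEO-FFI,MNI,,,,,
study_03,65,42,23,40.5,9.7,NEO-FFI,MNI,,,,,
study_04,116,58,58,22.9,5.5,NEO-PI-R,MNI,,,,,
study_05,32,0,32,33.2,7.8,16PF,MNI,,,,,
study_06,83,46,37,24.9,7.7,MPQ-BF,MNI,,,,,
study_07,87,42,45,72,7.7,NEO-PI-R,MNI,,,,,
study_08,337,189,148,20.0,1.3,NEO-PI-R,MNI,,,,,
study_09,71,37,34,22.35,1.5,EPQ-RSC,MNI,,,,,
study_10,41,22,19,23.8,5.4,NEO-PI-R,MNI,,,,,
study_11,364,182,182,29.1,3.45,NEO-FFI,MNI,,,,,
study_12,100,58,42,22.0,2.33,EPQ-RSC,MNI,,,,,
study_13,100,50,50,21.91,2.29,EPQ-RSC,MNI,,,,,
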