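patient_id,visit,diagnosis,cdr_global,cdr_sb,lacune_count,deep_mb_count,lobar_mb_count,wmh_deep_fazekas,wmh_pv_fazekas,bg_pvs_grade,cso_pvs_grade,css_extent,posterior_wmh_dominant,cmi_lesions,mmse,rcpm_score,rcpm_time_s,rbmt_sps,rbmt_ss,tmt_a_s,tmt_b_s,wf_animal,wf_letters,mcas_score,mcas_time_s
1,baseline,probable AD,1,,0,0,0,3,3,1,4,none,,[],23,,,,,,,,,,
2,baseline,aMCI,0.5,,0,0,3,1,1,1,1,none,,[],22,,,,,,,,,,
3,baseline,probable AD,1,,1,3,23,3,2,3,3,none,,[],27,,,,,,,,,,
4,baseline,aMCI,0.5,,0,3,43,2,3,2,4,none,,[],21,,,,,,,,,,
5,baseline,aMCI,0.5,,2,0,3,3,3,2,3,none,,[],23,,,,,,,,,,
6,baseline,naMCI,0.5,,0,0,0,2,3,3,3,none,,[],27,,,,,,,,,,
7,baseline,probable AD,1,,0,0,12,2,2,3,4,none,,[],25,,,,,,,,,,
8,baseline,aMCI,0.5,,0,0,0,2,1,1,4,none,,[],27,,,,,,,,,,
9,baseline,aMCI,0.5,,0,0,1,1,1,1,3,none,,[],26,,,,,,,,,,
1,follow_up,probable AD,2,,0,0,2,3,3,2,4,none,,[],16,,,,,,,,,,
2,follow_up,probable AD,1,,0,0,6,1,1,1,3,none,,[],15,,,,,,,,,,
3,follow_up,probable AD,2,,1,3,26,3,3,3,3,none,,[],21,,,,,,,,,,
4,follow_up,probable AD,1,,0,3,47,2,3,2,4,none,,[],10,,,,,,,,,,
5,follow_up,vascular dementia,1,,2,0,3,3,3,2,3,none,,[],19,,,,,,,,,,
6,follow_up,probable AD,1,,0,0,0,2,3,3,3,none,,[],27,,,,,,,,,,
7,follow_up,probable AD,2,,0,0,12,2,3,3,4,none,,[],22,,,,,,,,,,
8,follow_up,probable AD,1,,0,0,6,2,2,1,4,none,,[],26,,,,,,,,,,
9,follow_up,probable AD,1,,0,0,1,1,1,1,3,none,,[],26,,,,,,,,,,
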