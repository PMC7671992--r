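start_s,end_s,landmarks
0,6.2,out_of_patient
6.2,14.8,middle_nasal_concha
14.8,22.1,middle_nasal_concha;middle_nasal_meatus
22.1,30.5,middle_nasal_meatus
30.5,41.0,uncinate_process_of_ethmoid;ethmoidal_bulla
41.0,55.4,maxillary_sinus_orifice
55.4,63.9,middle_nasal_concha
63.9,70.0,out_of_patient
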