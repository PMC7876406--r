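subject_id	sex	age_years	age_months	deletion	autism	iq	seizure_history
D001	M	14	11	Yes	No	36	No
D002	M	14	2	Yes	Yes	82	No
D003	M	18	9	Yes	No	50	No
D004	M	15	5	Yes	Yes	55	History of frontal lobe epilepsy
D005	M	14	0	Yes	Yes	73	No
D006	M	18	11	Yes	Yes	67	History of generalized tonic-clonic seizures
D007	M	14	8	Yes	No	87	No
D008	M	18	8	Yes	No	59	No
D009	M	16	9	Yes	Yes	56	No
D010	F	15	0	Yes	No	67	No, myoclonic jerks
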