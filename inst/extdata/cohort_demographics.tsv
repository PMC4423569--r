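subject_id	group	age	sex	diagnosis	sampling_rate_hz	n_segments
PC01	control	12	M	-	200	11
PC02	control	15	F	-	512	20
PC03	control	12	M	-	200	14
PC04	control	15	F	-	512	18
PC05	control	10	M	-	512	3
PC06	control	18	F	-	512	20
PC07	control	8	M	-	512	5
PE01	epilepsy	10	F	Left temporal dysplasia	200	14
PE02	epilepsy	7	F	Left frontal region	512	67
PE03	epilepsy	4	F	Right fronto-centro-temporal	512	39
PE04	epilepsy	14	M	Generalized	512	18
PE05	epilepsy	8	M	Right parietal	200	30
PE06	epilepsy	7	M	Left frontal pole, posterior frontal lobe	512	77
PE07	epilepsy	15	F	Left and right frontal	500	40
PE08	epilepsy	4	M	Right fronto-centro-temporal	512	25
PE09	epilepsy	2	F	Left temporal (posterior)	512	25
PE10	epilepsy	14	M	Generalized	512	6
PE11	epilepsy	15	M	Generalized	512	13
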