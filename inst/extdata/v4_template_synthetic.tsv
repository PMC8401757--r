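helix	start	end	partner_helix
E23_1	6	9	E23_1
E23_1	14	17	E23_1
E23_2	21	24	E23_2
E23_2	29	32	E23_2
E23_3	36	39	E23_3
E23_3	44	47	E23_3
E23_4	51	54	E23_4
E23_4	59	62	E23_4
E23_5	66	69	E23_5
E23_5	74	77	E23_5
E23_6	81	84	E23_6
E23_6	89	92	E23_6
E23_7	96	99	E23_7
E23_7	104	107	E23_7
E23_8	111	114	E23_8
E23_8	119	122	E23_8
E23_9	126	130	E23_9
E23_10	133	136	E23_10
E23_10	141	144	E23_10
E23_11	148	151	E23_11
E23_11	156	159	E23_11
E23_9	165	169	E23_9
E23_12	173	176	E23_12
E23_12	181	184	E23_12
E23_13	188	191	E23_13
E23_13	196	199	E23_13
E23_14	203	206	E23_14
E23_14	211	214	E23_14
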