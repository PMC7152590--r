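tissue	stress	timepoint	down	up
leaf	Fe	T1	3314	1990
leaf	Fe	T1Rec	897	1492
leaf	Fe	T1T2	96	120
leaf	Fe	T2	881	950
leaf	Pi	T1	20	279
leaf	Pi	T1Rec	1589	2564
leaf	Pi	T1T2	277	627
leaf	Pi	T2	1091	2393
root	Fe	T1	3746	1965
root	Fe	T1Rec	29	472
root	Fe	T1T2	3905	6388
root	Fe	T2	3850	6249
root	Pi	T1	179	1018
root	Pi	T1Rec	6058	6537
root	Pi	T1T2	3816	6270
root	Pi	T2	3788	6032
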