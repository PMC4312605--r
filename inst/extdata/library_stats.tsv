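library	total_raw	clean_total	unique_total	clean_pct	unique_pct
C1	20653733	12005904	650391	58.13	3.15
T1	19546412	10544528	1046638	53.95	5.35
C2	19375732	10619535	846328	54.81	4.37
T2	21290140	11701889	1798773	54.96	8.45
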