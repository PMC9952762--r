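feature_id	WT_1	WT_2	WT_3	KO_1	KO_2	KO_3
M001	6163.92016227013	8514.59567480231	6516.89683304387	3987.20823538395	6084.83749279202	4739.53995583630
M002	5337.83502157521	7831.39368448819	6173.11756802444	6120.52246936500	6050.37912698595	5912.02626423343
M003	2155.84098082525	3527.33079157776	1405.61870507419	1929.81925195985	2222.00476691670	1132.07063669351
M004	4220.20937002197	4401.70976693476	2328.40888780346	2383.44335025163	2609.08143842379	3970.28465849377
M005	1048.43659648302	1292.76113651246	1116.77654360583	1995.35999303214	1169.72338896928	1369.78685893941
M006	1715.39183200315	1240.10098211975	1525.48805749931	2066.57387460548	1228.37753551698	1204.76456983407
M007	2639.58663863969	5562.08268726593	2972.51133196918	3164.69327381420	2153.69705014289	3478.98888867090
M008	3896.28308577090	3984.24748232118	2912.79876967532	4067.43624002028	3778.76805776425	3612.74171345271
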