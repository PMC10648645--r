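Chromosome	Position(bp)	Rate(cM/Mb)	Map(cM)
chr17	3e+07	1.87807308174098	0
chr17	30400000	1.94863378232043	0.751229232696392
chr17	30800000	1.96174898635217	1.53068274562457
chr17	31200000	1.92609221489971	2.31538234016543
chr17	31600000	1.8547763496089	3.08581922612532
chr17	3.2e+07	1.76390450261214	3.82772976596888
chr17	32400000	1.67083378268915	4.53329156701374
chr17	32800000	1.59232590747124	5.2016250800894
chr17	33200000	1.54276962605073	5.83855544307789
chr17	33600000	1.53265261058252	6.45566329349819
chr17	3.4e+07	1.56743557491255	7.06872433773119
chr17	34400000	1.64694134850288	7.69569856769621
chr17	34800000	1.76532043668766	8.35447510709737
chr17	35200000	1.91159729976357	9.06060328177243
chr17	35600000	2.07074385325662	9.82524220167786
chr17	3.6e+07	2.22517424246589	10.6535397429805
chr17	36400000	2.35651296664276	11.5436094399669
chr17	36800000	2.44746107728469	12.486214626624
chr17	37200000	2.48357516024599	13.4651990575378
chr17	37600000	2.45478212788216	14.4586291216362
chr17	3.8e+07	2.35647867791232	15.4405419727891
chr17	38400000	2.19010507097564	16.383133443954
chr17	38800000	1.96313460999214	17.2591754723443
chr17	39200000	1.68847776084413	18.0444293163411
chr17	39600000	1.38335754860764	18.7198204206788
chr17	4e+07	1.06776499540745	19.2731634401218
chr17	40400000	0.762644783170954	19.7002694382848
chr17	40800000	0.487987934022955	20.0053273515532
chr17	41200000	0.261017473039447	20.2005225251624
chr17	41600000	0.0982493805015139	20.3049295143782
chr17	4.2e+07	0.0612780636003762	20.3442292665788
chr17	42400000	0.0612780636003762	20.3687404920189
chr17	42800000	0.0612780636003762	20.3932517174591
chr17	43200000	0.096655538427699	20.4177629428992
chr17	43600000	0.225948301549197	20.4564251582703
chr17	4.4e+07	0.380378690758478	20.54680447889
chr17	44400000	0.53952524425152	20.6989559551934
chr17	44800000	0.685802107327431	20.914766052894
chr17	45200000	0.804181195512204	21.1890868958249
chr17	45600000	0.883686969102522	21.5107593740298
chr17	4.6e+07	0.918469933432577	21.8642341616708
chr17	46400000	0.908352917964361	22.2316221350439
chr17	46800000	0.858796636543842	22.5949633022296
chr17	47200000	0.780288761325938	22.9384819568472
chr17	47600000	0.687218041402939	23.2505974613775
chr17	4.8e+07	0.596346194406188	23.5254846779387
chr17	48400000	0.525030329115372	23.7640231557012
chr17	48800000	0.489373557662915	23.9740352873473
chr17	49200000	0.502488761694666	24.1697847104125
chr17	49600000	0.573049462274104	24.3707802150904
chr17	5e+07	0	24.6
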