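gene	0	10	20	30	40	50	60	70	80	90	100	110	120	130	140	150	160
CLN1	-1.91253022721233	0.149573056789307	-0.560916200774392	0.905415881242759	-2.94659962981717	1.03930496737212	-0.934425625962695	-0.102200752226245	1.50934636309263		1.56340323979808	-0.296947087580599	2.5987712629318	3.1035820670954	1.69091062223876	2.48740704036257	1.6499312941523
CLN2	-1.8461884879315	-0.0975391738010642	-0.514153879388069	0.810058546799983	-2.705379995915	1.08924756766203	-0.785557252815909	-0.193372112650902	1.88100740815649	3.859413280421	2.00433902166796	1.63025762268271	0.753163063591631	2.16820036495998	1.34124794765502	2.56019778792036	0.903170743047052
CDC28	-1.77448183799594	-0.139120704456916	-0.376669783978486	0.805729095415993	-2.40837219900069	0.85596862178104	-0.843562358204886	-0.0527348786404128	2.29399613489772	0.408284764188244	2.26916812257161	1.68811589635764	1.64157445185351	2.46616146272477	2.7692939138398	2.10344773526383	2.88091067035873
SWE1	-1.56924352713984	0.0803817681261063	-0.363246208683686	0.655641837652622	-2.113944772092	0.799325334041218	-0.821459604260942	-0.0459181590354794	2.17135044329325	1.16740241794793	2.61475617471925	1.21051505050203	1.78341127320928	0.613396701902463	2.68139109021423	0.926879674991278	2.65058347479666
CDC5	0.418331300862955	-0.323692704835646	-1.61800265019688	0.417319159877582	0.290552322843664	0.423912852198897	0.868270351339606	0.219755617894905	1.54360442013133	3.35229879181108	3.73622261408171	2.2165676451202	3.51324433700203	1.55567806977473	0.220865658819585	1.99135513357274	1.03012608429633
CDH1	-1.29752415174735	0.755898120811562	0.302778851978273	0.919674926753318	0.950195171098196	0.724031843095473	-1.01151414120972	-0.836816912691908	1.40347525582109	2.97388773721666	3.47900370515381	1.98496142852413	3.32748614526059	1.34323654572253	0.0753269529169101	1.74249810394	0.888949328601167
SWI5		-0.76539037720101	-0.58766072172824	-0.115421024165978		1.42594325794125	0.264132832171694	0.429319378566306	1.17555352825428	2.67603256199921	3.12754998332734	1.85929632804695	2.97657700445637	1.03845856692866	-0.0433633296507413	1.82136645106599	0.778232308415705
SIC1	-0.60957562044897		0.1320075399051	-0.889504194660977	0.185801842425187	-1.39576924469688	1.20764722771368	0.400124417258702		2.48756340725904	2.78025104578445	1.68975096311317	2.72240427083058	1.04740150212172	0.108562292108752	1.68248471699376	0.65545016924914
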