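node_u	node_v	confidence
G0001	G0002	0.536126555642113
G0001	G0003	0.526564741740003
G0002	G0003	0.765937218209729
G0001	G0004	0.556154120829888
G0003	G0004	0.871593859861605
G0001	G0005	0.865657738642767
G0002	G0005	0.942558843526058
G0002	G0006	0.75855552777648
G0003	G0006	0.925965492497198
G0006	G0007	0.721398134133779
G0003	G0007	0.578940050210804
G0006	G0008	0.72116231941618
G0007	G0008	0.983866833616048
G0001	G0009	0.742293964722194
G0007	G0009	0.626229219720699
G0004	G0010	0.629844990093261
G0003	G0010	0.771007970441133
G0002	G0011	0.824937918805517
G0008	G0011	0.668209566152655
G0009	G0012	0.530474873143248
G0003	G0012	0.725655425107107
G0006	G0013	0.919377516722307
G0008	G0013	0.787318667164072
G0011	G0014	0.676675188704394
G0003	G0014	0.773713039117865
G0005	G0015	0.946359296911396
G0012	G0015	0.744995285291225
G0003	G0016	0.585816056584008
G0012	G0016	0.771515497006476
G0001	G0017	0.980733847944066
G0015	G0017	0.656841911026277
G0012	G0018	0.910257274052128
G0014	G0018	0.653527200222015
G0005	G0019	0.592726790579036
G0004	G0019	0.524173388374038
G0002	G0020	0.62283707363531
G0015	G0020	0.675553461071104
G0003	G0021	0.579511190881021
G0020	G0021	0.652048998395912
G0003	G0022	0.508774162386544
G0012	G0022	0.998276339611039
G0019	G0023	0.902196656330489
G0008	G0023	0.543290300876833
G0006	G0024	0.934966634842567
G0007	G0024	0.777292931685224
G0003	G0025	0.710689210915007
G0017	G0025	0.533818409545347
G0007	G0026	0.780718978261575
G0018	G0026	0.535360947134905
G0023	G0027	0.605695969425142
G0014	G0027	0.774810206727125
G0027	G0028	0.740990724181756
G0004	G0028	0.579734927276149
G0012	G0029	0.574789497535676
G0002	G0029	0.749636440188624
G0001	G0030	0.97028243902605
G0027	G0030	0.66711566329468
G0003	G0031	0.594217164791189
G0009	G0031	0.63485808914993
G0011	G0032	0.765372039051726
G0001	G0032	0.510725114261732
G0002	G0033	0.89938015374355
G0005	G0033	0.55516755010467
G0023	G0034	0.76989914290607
G0032	G0034	0.785616948734969
G0017	G0035	0.809475773479789
G0014	G0035	0.857426846749149
G0013	G0036	0.561650289339013
G0002	G0036	0.655524809379131
G0006	G0037	0.972869581310079
G0026	G0037	0.750012546195649
G0013	G0038	0.567615249543451
G0012	G0038	0.934628910268657
G0003	G0039	0.602524806046858
G0001	G0039	0.962522945483215
G0012	G0040	0.943376799114048
G0027	G0040	0.568147912621498
G0001	G0041	0.892674721078947
G0018	G0041	0.726651707082056
G0003	G0042	0.567871209699661
G0014	G0042	0.942610518424772
G0013	G0043	0.668356770067476
G0003	G0043	0.659637057571672
G0009	G0044	0.701891407370567
G0001	G0044	0.739538653520867
G0014	G0045	0.683950910111889
G0011	G0045	0.732845283811912
G0025	G0046	0.524946076446213
G0008	G0046	0.593678355799057
G0002	G0047	0.99132970685605
G0003	G0047	0.664137034793384
G0003	G0048	0.585498195257969
G0008	G0048	0.74412744725123
G0025	G0049	0.509343705838546
G0003	G0049	0.669742541853338
G0002	G0050	0.51483168778941
G0036	G0050	0.933614331530407
G0038	G0051	0.865853799856268
G0032	G0051	0.657630398403853
G0008	G0052	0.693227005889639
G0005	G0052	0.666222995263524
G0029	G0053	0.544888985576108
G0018	G0053	0.878527801251039
G0017	G0054	0.8014842486009
G0012	G0054	0.572699986281805
G0012	G0055	0.516258741728961
G0009	G0055	0.741884070797823
G0037	G0056	0.722284763935022
G0034	G0056	0.530192794976756
G0034	G0057	0.663753011031076
G0036	G0057	0.939214523648843
G0011	G0058	0.965302443131804
G0003	G0058	0.696089228498749
G0036	G0059	0.579423387418501
G0048	G0059	0.659973800531588
G0030	G0060	0.65348281012848
G0017	G0060	0.553905627224594
G0004	G0061	0.989667151705362
G0018	G0061	0.748451714054681
G0003	G0062	0.546537335962057
G0009	G0062	0.605886829085648
G0034	G0063	0.965250373119488
G0050	G0063	0.648423203383572
G0018	G0064	0.826609124429524
G0017	G0064	0.950535238953307
G0023	G0065	0.995397896622308
G0015	G0065	0.715166610665619
G0037	G0066	0.696888461126946
G0007	G0066	0.570954447728582
G0010	G0067	0.639903348172083
G0063	G0067	0.78241111128591
G0008	G0068	0.967569752712734
G0063	G0068	0.67920007253997
G0041	G0069	0.921003590454347
G0063	G0069	0.861204607179388
G0030	G0070	0.875367994653061
G0062	G0070	0.96199422609061
G0046	G0071	0.50118905340787
G0034	G0071	0.5802149574738
G0051	G0072	0.699636475648731
G0012	G0072	0.837659788667224
G0061	G0073	0.740186008159071
G0032	G0073	0.766914390376769
G0002	G0074	0.658475078642368
G0012	G0074	0.907378795091063
G0027	G0075	0.646109760622494
G0056	G0075	0.704566045664251
G0062	G0076	0.545459153829142
G0024	G0076	0.899298319010995
G0001	G0077	0.679892624844797
G0067	G0077	0.520243788370863
G0018	G0078	0.520543169928715
G0002	G0078	0.977217119187117
G0010	G0079	0.686670622439124
G0009	G0079	0.90320983377751
G0057	G0080	0.955029504490085
G0034	G0080	0.720038106432185
G0029	M001	0.788168251514435
G0063	M002	0.536833897582255
G0014	M003	0.582313697203062
G0006	M004	0.86994538793806
G0047	M004	0.737855506362393
G0043	M004	0.842760476632975
G0037	M005	0.975757471402176
G0031	M005	0.748732243780978
G0006	M006	0.735250313300639
G0038	M006	0.780095975031145
G0006	M007	0.826255060266703
G0015	M007	0.639786749379709
G0034	M007	0.989953794749454
G0060	M008	0.821932054008357
G0012	M008	0.791289217886515
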