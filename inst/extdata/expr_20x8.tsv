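# synthetic 20-gene x 8-sample cohort, 2 planted classes (seed 42)
gene	s001	s002	s003	s004	s005	s006	s007	s008
g0001	11.064319853068193	11.576957047346921	11.003723804405693	12.883665456951597	9.571923822745163	6.877333379830377	8.284851148909578	8.19543257690454
g0002	7.653993394623912	9.074244530055246	9.62053239346952	9.693223266135943	7.480052915771637	4.964866087167115	5.54762281069748	5.363519444453235
g0003	10.191211055577718	11.121291647036855	10.944952138702845	10.451568640496925	6.359919764497491	7.487830797534346	6.9184444064526005	7.526335293804721
g0004	11.84753730413364	9.906157777884465	12.032599432253718	10.511966067421952	9.481344506633787	6.636223470077003	7.603417725872802	7.270124189333091
g0005	9.299461784405965	6.035987278721705	6.676976263666535	6.209939427980471	9.737494914383182	10.402445708836293	9.990399474083077	10.994281871128338
g0006	6.463406352302317	7.326693509797233	8.19641811595266	7.505872381948903	9.999389296364585	9.4656166024827	11.00726150727672	11.326297411639507
g0007	8.254252614670008	7.700128821252267	8.847370117191014	8.294382151692417	11.089266115570084	10.897850390989444	11.030529155784956	10.518829486329446
g0008	5.142177876392122	8.349442223308156	7.943847060284524	6.722584255254981	9.78299078963193	7.880663116167794	9.472171928986173	10.359991259167185
g0009	9.478521068708313	8.586977511263695	9.939152282167688	9.951770042448201	9.20661674837854	7.793675763517055	9.715286290429145	9.103321772555528
g0010	6.29729102498746	7.5929337843497855	7.658164063814441	7.759059011455828	7.056446858944585	7.116802342065517	5.880917487776671	7.832851483212123
g0011	8.760319777464703	8.62679491942743	7.261750715655629	9.696986030157756	8.279777103356082	8.87249024864702	8.26417117907227	8.075091515277219
g0012	9.991482729929926	8.502806451820732	9.1964590060904	8.810471469646433	9.39471812064314	8.793768039147633	7.735100570353517	10.123264461161721
g0013	6.646242820857584	7.186866818679638	6.234657460887204	6.2614878596139665	5.125704063040994	5.611202182953012	6.778308848123343	3.8660834375509676
g0014	6.112284857775418	7.364110538899945	5.767687875410285	8.11232168957263	6.216994102494725	7.844100876562595	6.447565531808548	8.410670154496003
g0015	7.371633786904312	6.956439310205948	6.323849849032485	5.755889784158443	5.20557958369153	8.306534406582532	6.398833338934089	7.73145664212492
g0016	5.918941718996732	7.912501145361537	8.216946895751757	6.775157811192232	7.253616671196256	6.538836629664252	6.39769807008386	7.485174409184326
g0017	5.931288070204431	7.395035894639198	7.483925816418518	5.584008397730157	6.203096820706127	6.59842751833375	6.707985044806601	5.2667399484447595
g0018	3.4926369849187067	4.433377465674306	4.807312167635392	2.884330579592829	7.0454355794400225	5.545042980014926	3.543262401143565	4.9865532791372065
g0019	2.1453254214778488	1.5664429882715458	3.673756774014801	4.639515624665642	3.1974168402347622	4.08980349085818	4.026040741474044	5.042726935239248
g0020	8.356235952622448	8.60499629926085	7.2203324470823365	8.973317685379381	8.457369564288799	8.267643860791196	9.607788591314781	8.313757719308803
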