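locus	class	locus_index	introgressed	donor	newick
X_0001	X	1	FALSE	NA	((((a3_1:0.3526432948,a3_2:0.3526432948):2.811843522,(a4_1:0.8539047395,a4_2:0.8539047395):2.310582078):0.6852101739,((a1_1:0.01174787806,a1_2:0.01174787806):1.398662658,(a2_1:0.4841315235,a2_2:0.4841315235):0.926279013):2.439286454):3.081138961,(((b3_1:1.552502338,b3_2:1.552502338):0.6138053215,((b2_1:0.04163021167,b2_2:0.04163021167):1.953147803,(b1_1:0.07993767706,b1_2:0.07993767706):1.914840337):0.1715296451):2.481566969,(b4_1:1.99452689,b4_2:1.99452689):2.653347738):2.282961324);
X_0002	X	2	FALSE	NA	((((a4_1:0.1917820644,a4_2:0.1917820644):3.142410364,((a2_2:0.1241188293,a2_1:0.1241188293):0.997867035,a1_2:1.121985864):2.212206564):0.8455818282,(a1_1:3.002392066,(a3_2:0.5124580056,a3_1:0.5124580056):2.489934061):1.177382191):1.910179887,(((b1_2:0.570120411,b1_1:0.570120411):1.439435158,(b3_1:0.4743006171,b3_2:0.4743006171):1.535254952):1.6262615,((b2_1:1.151692949,b2_2:1.151692949):2.137393339,(b4_2:0.3293755926,b4_1:0.3293755926):2.959710696):0.3467307809):2.454137074);
X_0003	X	3	FALSE	NA	(((b4_2:0.08705677021,b4_1:0.08705677021):5.203176049,(((b1_2:0.6141307066,b1_1:0.6141307066):0.9224301637,(b2_2:0.1498633376,b2_1:0.1498633376):1.386697533):1.296951695,(b3_2:0.2570692744,b3_1:0.2570692744):2.57644329):2.456720255):1.758939046,((a3_2:1.480031393,a3_1:1.480031393):2.147979482,(((a1_1:0.002682008679,a1_2:0.002682008679):1.898491439,(a2_2:0.06649980637,a2_1:0.06649980637):1.834673641):1.457555846,(a4_2:0.0592287696,a4_1:0.0592287696):3.299500524):0.2692815819):3.42116099);
X_0004	X	4	FALSE	NA	((((((a1_2:0.1737107616,a1_1:0.1737107616):1.128930758,a2_1:1.302641519):0.5370077327,a2_2:1.839649252):1.310876735,(a3_2:0.4130060777,a3_1:0.4130060777):2.73751991):0.2232335038,(a4_2:1.263682138,a4_1:1.263682138):2.110077353):3.401838798,(((b3_1:1.171078037,b3_2:1.171078037):1.640961822,((b1_2:0.01730839671,b1_1:0.01730839671):1.46562278,(b2_1:0.5628480008,b2_2:0.5628480008):0.9200831761):1.329108682):0.3331255166,(b4_1:1.918446475,b4_2:1.918446475):1.226718901):3.630432913);
rearranged_0001	rearranged	1	FALSE	NA	((((a3_2:0.01036503247,a3_1:0.01036503247):2.462424878,((a2_2:0.8637687302,a2_1:0.8637687302):1.025547948,(a1_2:0.3631886945,a1_1:0.3631886945):1.526127984):0.5834732322):1.200008664,(a4_2:1.296634508,a4_1:1.296634508):2.376164067):2.460100985,((b4_2:0.04298006299,b4_1:0.04298006299):2.99429284,((b3_1:1.501290726,b3_2:1.501290726):0.5493616665,((b1_1:0.04925963157,b1_2:0.04925963157):1.494004594,(b2_2:0.1228259597,b2_1:0.1228259597):1.420438265):0.5073881672):0.9866205107):3.095626656);
rearranged_0002	rearranged	2	FALSE	NA	(((((a2_1:0.1754459928,a2_2:0.1754459928):1.445349831,(a1_1:0.0776986944,a1_2:0.0776986944):1.54309713):1.731075012,(a3_1:0.1029113994,a3_2:0.1029113994):3.248959436):0.9092153804,(a4_1:0.5361968688,a4_2:0.5361968688):3.724889347):4.003761977,((b1_2:1.404179754,((b2_1:1.024819214,b2_2:1.024819214):0.3195756819,b1_1:1.344394896):0.05978485805):2.221980857,((b4_2:0.7396343166,b4_1:0.7396343166):2.359891493,(b3_1:1.987120999,b3_2:1.987120999):1.11240481):0.5266348016):4.638687582);
rearranged_0003	rearranged	3	FALSE	NA	(((a4_2:0.4116324547,a4_1:0.4116324547):4.266946558,((a3_1:0.7081543918,a3_2:0.7081543918):2.122579224,((a2_1:0.05894071353,a2_2:0.05894071353):2.273012115,(a1_1:1.339722669,a1_2:1.339722669):0.9922301602):0.498780787):1.847845397):2.250707689,(((((b1_1:0.2653393951,b1_2:0.2653393951):0.9080951344,b2_2:1.173434529):0.1092779738,b2_1:1.282712503):1.871402228,(b3_2:0.3867708096,b3_1:0.3867708096):2.767343922):0.712818614,(b4_1:0.08658628892,b4_2:0.08658628892):3.780347057):3.062353356);
rearranged_0004	rearranged	4	FALSE	NA	(((a4_1:0.4143146597,a4_2:0.4143146597):3.533961815,(a1_1:2.492881767,((a1_2:1.407877472,(a2_2:1.205863033,a2_1:1.205863033):0.2020144388):0.8022691572,(a3_2:0.1805733023,a3_1:0.1805733023):2.029573327):0.2827351377):1.455394708):2.387465336,(((b4_2:0.6945704011,b4_1:0.6945704011):2.31449716,(b3_1:0.5109722197,b3_2:0.5109722197):2.498095341):0.6026913579,((b2_1:0.442046547,b2_2:0.442046547):2.779976488,(b1_2:0.8412551697,b1_1:0.8412551697):2.380767865):0.389735884):2.723982892);
non_rearranged_0001	non_rearranged	1	TRUE	a4	(((b3_2:1.884456498,b3_1:1.884456498):2.026519016,(((b2_2:0.7869867784,b2_1:0.7869867784):1.357900887,(b1_2:0.6533383437,b1_1:0.6533383437):1.491549321):1.034962855,(b4_2:0.2810201323,b4_1:0.2810201323):2.898830388):0.731124994):3.629337804,(((a2_1:1.895067753,a2_2:1.895067753):0.5973957915,(a3_2:0.08605837647,a3_1:0.08605837647):2.406405168):1.348606308,((a1_2:0.4864507365,(a1_1:0.1155749298,a4_1:0.1155749298):0.3708758067):1.731784699,a4_2:2.218235436):1.622834416):3.699243466);
non_rearranged_0002	non_rearranged	2	TRUE	a4	(((b4_2:0.7999837896,b4_1:0.7999837896):2.629274511,((b3_2:0.5797407154,b3_1:0.5797407154):2.181688669,((b2_2:0.3134441479,b2_1:0.3134441479):0.8753229533,(b1_2:0.7773894901,b1_1:0.7773894901):0.4113776111):1.572662284):0.6678289155):4.765251801,(((a1_2:0.3437863535,a4_1:0.3437863535):0.1630405238,(a4_2:0.1470809324,a1_1:0.1470809324):0.3597459449):3.066916919,((a3_1:0.08935243844,a3_2:0.08935243844):2.262829818,(a2_1:2.055332241,a2_2:2.055332241):0.2968500154):1.22156154):4.620766305);
non_rearranged_0003	non_rearranged	3	TRUE	a4	(((((a4_2:0.1541780871,a1_2:0.1541780871):0.1619572171,a1_1:0.3161353042):0.1210427544,a4_1:0.4371780586):3.268262307,((a2_2:1.153157883,a2_1:1.153157883):1.762619595,(a3_2:0.16022759,a3_1:0.16022759):2.755549888):0.789662887):5.847544891,(((b1_2:2.163507935,(b1_1:1.579153414,(b2_1:0.2554059275,b2_2:0.2554059275):1.323747486):0.5843545218):0.8559567153,(b4_1:0.06857509195,b4_2:0.06857509195):2.950889559):0.1573395017,(b3_2:0.5556410465,b3_1:0.5556410465):2.621163106):6.376181104);
non_rearranged_0004	non_rearranged	4	TRUE	a4	((b3_2:3.990626604,((b4_1:0.4842632239,b4_2:0.4842632239):2.644771362,(((b2_2:0.2994550551,b2_1:0.2994550551):1.505723793,(b1_1:0.4417041612,b1_2:0.4417041612):1.363474687):0.5638841815,b3_1:2.369063029):0.7599715563):0.8615920187):3.224584768,(((a1_2:0.6912220072,a4_1:0.6912220072):2.683480705,((a3_1:0.889952756,a3_2:0.889952756):2.010539632,(a2_2:0.8598562521,a2_1:0.8598562521):2.040636136):0.4742103241):0.279846756,(a1_1:0.2179881155,a4_2:0.2179881155):3.436561352):3.560661905);
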