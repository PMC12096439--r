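concentration_mM,response,replicate
0,0.00445270452731608,1
0,0.00448717217453266,2
0,0.00443075852565243,3
0.5,0.00478893789263959,1
0.5,0.00442570083874628,2
0.5,0.00444646199933558,3
1,0.00571001029438481,1
1,0.00553041294785919,2
1,0.00544802786811682,3
2,0.0162951532493904,1
2,0.0149156924368089,2
2,0.0156176173903334,3
5,0.0831270631655771,1
5,0.0807139600397725,2
5,0.0807386602699048,3
10,0.160265003501386,1
10,0.170957577319512,2
10,0.144712097933768,3
15,0.181888360364621,1
15,0.17738143465558,2
15,0.194618685357263,3
20,0.173815972779335,1
20,0.189615264867675,2
20,0.182678888013731,3
30,0.14185179602859,1
30,0.15302817506348,2
30,0.139263497273499,3
50,0.0843925652449805,1
50,0.0853924465259221,2
50,0.0777751723036077,3
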