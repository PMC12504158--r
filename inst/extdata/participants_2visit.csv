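"visit_1","visit_2"
1.767634,9.899912
-3.017649,5.146147
5.00907,4.181881
6.693214,9.651802
10.829755,5.47909
8.79049,14.762822
10.120423,1.519438
10.41884,6.607021
7.870665,8.691838
-1.150867,7.684292
7.381605,13.632098
7.837583,-0.211001
7.990762,3.630298
3.990234,16.475939
9.324213,4.947233
3.488342,1.141793
1.823521,10.789461
4.099266,12.154092
3.240514,10.035
5.403865,5.132422
2.928279,3.922532
15.071093,11.380483
7.218238,11.168407
7.084593,15.977787
4.584599,6.560242
15.32289,14.510633
8.615211,13.813645
6.724922,7.056069
0.989241,1.545721
-0.450545,2.712901
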