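time_s,roi_mean,total_mean,background_mean,corrected_roi
0.0,1050.0,1050.0,50.0,999.0008328335693
1.0,1049.000499833375,1049.000499833375,50.0,999.0008328335693
2.0,1048.001998667333,1048.001998667333,50.0,999.0008328335693
3.0,448.8017982013492,1044.0134820168628,50.0,400.8027413575003
4.0,527.5854204819382,1043.0199653759596,50.0,480.4618733219451
5.0,594.4346344637594,1042.0274417551043,50.0,548.2617016022047
6.0,651.1364736799951,1041.0359101617735,50.0,605.9677875395258
7.0,699.2104055498042,1040.0453696044356,50.0,655.0828434131269
8.0,739.9483930712277,1039.0558190925494,50.0,696.885864260653
9.0,774.4489582237701,1038.067257636565,50.0,732.4654339240959
10.0,803.6461451826646,1037.0796842479203,50.0,762.7480726370519
11.0,828.334146977307,1036.0930979390428,50.0,788.5223643469834
12.0,849.1882448904585,1035.1074977233447,50.0,810.4594920671129
13.0,866.7826126780163,1034.1228826152267,50.0,829.1307160148052
14.0,881.6054550282645,1033.1392516300734,50.0,845.0222496810369
15.0,894.071879395156,1032.1566037842535,50.0,858.5479212156125
16.0,904.5348405792091,1031.1749380951192,50.0,870.0599498406389
17.0,913.2944466164564,1030.194253581005,50.0,879.8581179186259
18.0,920.605871330776,1029.2145492612258,50.0,888.1975775231465
19.0,926.6860821687858,1028.2358241560776,50.0,895.295494801344
20.0,931.7195607006995,1027.258077286835,50.0,901.3367051527708
21.0,935.8631666115724,1026.2813076757511,50.0,906.4785264898961
22.0,939.2502734249798,1025.3055143460565,50.0,910.8548559214101
23.0,941.99428499996,1024.3306963219572,50.0,914.5796565392092
24.0,944.1916255157688,1023.3568526286356,50.0,917.749925107761
25.0,945.9242817771841,1022.3839822922477,50.0,920.4482179368372
26.0,947.2619648697637,1021.412084339923,50.0,922.7448007133465
27.0,948.2639481583898,1020.4411577997638,50.0,924.6994782755904
28.0,948.9806300890331,1019.4712017008432,50.0,926.3631519787206
29.0,949.454862997943,1018.502215073205,50.0,927.7791452064267
30.0,949.7230829631095,1017.5341969478626,50.0,928.9843315462346
31.0,949.8162704872124,1016.5671463567978,50.0,930.0100950069907
32.0,949.7607673410345,1015.60106233296,50.0,930.8831472833633
33.0,949.5789711039083,1014.6359439102649,50.0,931.6262233495722
34.0,949.2899257131683,1013.6717901235941,50.0,932.2586734961621
35.0,948.9098235927993,1012.7086000087937,50.0,932.7969672269268
36.0,948.452432600206,1011.7463726026737,50.0,933.25512213786
37.0,947.9294590478064,1010.7851069430063,50.0,933.6450689464807
38.0,947.3508563707354,1009.824802068526,50.0,933.9769621771867
39.0,946.7250875788643,1008.8654570189276,50.0,934.2594445931298
40.0,946.059348412842,1007.9070708348662,50.0,934.4998722606279
41.0,945.3597570878012,1006.9496425579555,50.0,934.7045061069705
42.0,944.6315156274344,1005.9931712307671,50.0,934.8786749599345
43.0,943.8790470421112,1005.0376558968295,50.0,935.0269143146892
44.0,943.1061119678196,1004.0830956006275,50.0,935.1530844416902
45.0,942.3159078411843,1003.1294893876005,50.0,935.2604709111861
46.0,941.5111532253758,1002.1768363041425,50.0,935.3518701520753
47.0,940.6941595102076,1001.2251353976,50.0,935.4296622731343
48.0,939.866891876844,1000.2743857162723,50.0,935.4958730429393
49.0,939.0310211344821,999.3245863094094,50.0,935.5522266424875
50.0,938.1879677957202,998.3757362272119,50.0,935.600190564239
51.0,937.3389395526814,997.4278345208296,50.0,935.6410138267855
52.0,936.4849631419751,996.4808802423609,50.0,935.6757595002849
53.0,935.6269114386347,995.5348724448513,50.0,935.7053323896531
54.0,934.7655264933778,994.5898101822929,50.0,935.7305025964009
55.0,933.9014391205849,993.6456925096234,50.0,935.7519255726902
56.0,933.0351855534382,992.702518482725,50.0,935.7701591898266
57.0,932.1672216053496,991.7602871584238,50.0,935.7856782656726
58.0,931.29793471105,990.8189975944881,50.0,935.7988869292807
59.0,930.4276541648087,989.8786488496285,50.0,935.8101291447349
60.0,929.5566598257234,988.939239983496,50.0,935.8196976682483
61.0,928.685189519598,988.0007700566816,50.0,935.8278416717684
62.0,927.8134453325645,987.0632381307156,50.0,935.8347732316105
63.0,926.9415989623834,986.1266432680658,50.0,935.8406728510943
64.0,926.0697962685142,985.1909845321372,50.0,935.8456941609937
65.0,925.1981611409202,984.2562609872713,50.0,935.8499679202041
66.0,924.32679878961,983.322471698744,50.0,935.8536054208074
67.0,923.4557985416506,982.3896157327663,50.0,935.8567013862065
68.0,922.5852362193898,981.4576921564819,50.0,935.8593364377973
69.0,921.7151761626009,980.5267000379673,50.0,935.8615791944151
70.0,920.8456729478542,979.5966384462304,50.0,935.8634880592218
71.0,919.976772850457,978.6675064512093,50.0,935.8651127405727
72.0,919.1085150874994,977.7393031237722,50.0,935.866495546459
73.0,918.2409328747863,976.8120275357154,50.0,935.867672486244
74.0,917.3740543255159,975.8856787597633,50.0,935.8686742083738
75.0,916.5079032144041,974.9602558695672,50.0,935.8695267984873
76.0,915.6424996273993,974.0357579397041,50.0,935.8702524587081
77.0,914.7778605141158,973.1121840456758,50.0,935.8708700858044
78.0,913.9140001575554,972.1895332639086,50.0,935.871395763276
79.0,913.0509305734977,971.2678046717515,50.0,935.8718431801813
80.0,912.188661850092,970.3469973474758,50.0,935.8722239876115
81.0,911.3272024366025,969.4271103702742,50.0,935.8725481020946
82.0,910.4665593889212,968.5081428202595,50.0,935.872823963829
83.0,909.6067385783202,967.5900937784643,50.0,935.873058756473
84.0,908.7477448689492,966.6729623268393,50.0,935.8732585942136
85.0,907.8895822687557,965.756747548253,50.0,935.8734286809841
86.0,907.0322540578087,964.8414485264905,50.0,935.8735734459788
87.0,906.1757628974102,963.9270643462528,50.0,935.8736966589935
88.0,905.320110922867,963.0135940931557,50.0,935.8738015285927
89.0,904.4652998223742,962.1010368537287,50.0,935.8738907856639
90.0,903.6113309040867,961.1893917154144,50.0,935.8739667545321
91.0,902.7582051531491,960.2786577665679,50.0,935.874031413487
92.0,901.9059232801852,959.3688340964551,50.0,935.874086446299
93.0,901.0544857625284,958.4599197952522,50.0,935.8741332860664
94.0,900.2038928792774,957.5519139540447,50.0,935.8741731525336
95.0,899.3541447411051,956.6448156648268,50.0,935.8742070838554
96.0,898.5052413156019,955.7386240205,50.0,935.8742359636301
97.0,897.6571824488266,954.8333381148728,50.0,935.8742605439103
98.0,896.8099678836271,953.9289570426591,50.0,935.8742814647856
99.0,895.9635972752225,953.0254798994779,50.0,935.8742992710522
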