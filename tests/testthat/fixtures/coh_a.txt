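0.000369
0.677409
0.868815
0.683879
0.451384
-0.297494
-0.569742
-0.548992
-1.098718
-0.773928
0.146953
0.694851
0.982681
0.671916
0.579010
0.208591
-0.991050
-1.088341
-1.521423
-0.974647
-0.552521
0.517258
0.570823
1.032436
0.634811
-0.056079
-1.342813
-1.112664
-0.965607
-0.553793
-0.459041
0.444459
0.657501
0.708405
0.906055
-0.242260
-0.597542
-0.685740
-1.126137
-0.621296
0.033139
0.606920
0.583540
0.973899
0.995432
-0.464143
-0.329970
-0.915250
-1.143498
0.012340
0.228678
0.227999
0.973411
1.124063
0.531151
0.204873
-0.607740
-0.750882
-0.519500
-0.790484
0.060942
0.448793
0.989237
0.594898
0.413995
-0.058859
-0.318156
-0.607490
-1.348115
-0.826178
0.194071
-0.009941
0.812106
0.921870
0.964890
0.206821
-0.685949
-1.061629
-1.026115
-0.130726
-0.128407
0.496681
1.056833
0.914825
0.528600
-0.334220
-0.591242
-1.084131
-0.601218
-0.391859
-0.007243
0.788300
0.849096
1.266694
0.586165
0.175015
-0.975053
-0.847053
-1.457518
-1.198384
-0.091343
0.317807
1.000272
1.624484
0.338268
-0.187183
-0.526164
-0.803153
-1.003978
-0.649564
0.210739
0.743758
0.640954
0.927302
0.598371
-0.316345
-0.509834
-1.208443
-0.659437
-0.529961
0.026792
0.410477
0.915474
0.351733
0.248363
0.108852
-1.226355
-0.697074
-1.474885
-0.360764
-0.253649
0.821483
0.990342
0.490006
0.962530
0.432512
-0.607527
-1.033231
-0.999017
-0.880331
0.329576
0.424918
0.935699
0.713068
0.399963
-0.383318
-0.210664
-0.997283
-0.661280
-0.583788
-0.208321
0.489780
0.782987
0.953444
0.475205
-0.089977
-1.001358
-1.193110
-0.454839
-0.789155
-0.316228
0.688983
1.373238
0.514849
0.525229
-0.189616
-1.116091
-0.730579
-0.958090
-0.566353
-0.225693
0.724221
0.789267
0.908186
0.255307
-0.364831
-0.187126
-1.103188
-0.863552
-0.597922
-0.132344
0.435397
1.140081
0.860496
0.542352
0.006666
-0.234833
-0.746903
-0.836276
-0.756857
-0.414591
0.872644
1.240991
0.908844
0.750350
0.234433
-0.338430
-0.674641
-1.087742
-0.133293
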