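-0.373978
0.846302
1.099236
1.213142
1.151488
0.445334
-0.931338
-1.457658
-0.705990
-0.892289
-0.003722
0.839703
0.457917
0.318062
0.665575
0.013316
-0.661526
-0.939496
-1.209211
-1.041834
-0.049996
0.296273
0.458012
1.102761
0.569366
0.121959
-0.884574
-1.148474
-1.250769
-0.853778
0.058622
0.352893
1.057876
1.052983
1.195334
-0.417837
-0.321415
-0.977903
-0.955265
-1.022744
-0.138058
0.810744
0.926313
0.975373
0.500570
0.346371
-0.594227
-1.611181
-1.158678
-1.178424
-0.975432
0.428751
1.351124
0.965192
0.236022
-0.282210
-0.248601
-0.903769
-0.936657
-0.603824
0.011520
0.829407
1.116827
1.015768
0.274925
0.153333
-0.793059
-0.622903
-1.332372
-0.629072
-0.002207
0.190392
1.467648
1.389179
0.448710
0.231516
-0.474182
-1.735124
-0.875937
-0.606188
0.024965
0.264723
0.870252
0.897579
0.944214
0.100328
-0.589452
-0.492366
-1.117631
-0.704614
-0.545027
1.058517
1.240356
1.226111
0.788455
0.033045
-0.523139
-1.026658
-1.012137
-0.571494
0.453549
0.754492
0.933518
0.777239
0.397286
0.480812
-0.435779
-0.930791
-1.054911
-0.920501
-0.020058
0.849883
0.833295
0.882884
0.521475
0.032878
-1.065689
-1.021676
-1.207375
-0.322410
-0.231180
0.760899
1.408388
0.856978
0.407312
0.057430
-0.588394
-1.249141
-0.812781
0.016870
-0.077434
0.526922
0.637577
1.046783
0.213692
-0.332079
-0.203885
-1.222692
-0.626649
-0.130478
0.077798
0.753803
1.536732
0.892038
0.409884
-0.405969
-0.575273
-0.507313
-0.663178
-0.870413
-0.256613
0.436534
1.038737
0.889463
0.652121
0.089022
-0.677417
-0.963109
-0.889079
-0.612976
0.151056
1.149048
1.128648
0.967800
0.081950
0.116387
-1.171789
-1.373767
-0.694665
-0.375915
-0.044982
0.074782
0.839652
0.747435
0.778837
0.677319
-0.522706
-1.184850
-1.302222
-0.604614
-0.053038
0.242330
0.985963
0.605782
0.921417
0.318795
-0.262360
-1.093272
-0.796700
-0.627406
-0.116644
0.486042
0.561142
0.517897
0.826080
-0.057371
-0.522858
-0.650543
-1.470996
-0.823024
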