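0.304717
-1.039984
0.750451
0.940565
-1.951035
-1.302180
0.127840
-0.316243
-0.016801
-0.853044
0.879398
0.777792
0.066031
1.127241
0.467509
-0.859292
0.368751
-0.958883
0.878450
-0.049926
-0.184862
-0.680930
1.222541
-0.154529
-0.428328
-0.352134
0.532309
0.365444
0.412733
0.430821
2.141648
-0.406415
-0.512243
-0.813773
0.615979
1.128972
-0.113947
-0.840156
-0.824481
0.650593
0.743254
0.543154
-0.665510
0.232161
0.116686
0.218689
0.871429
0.223596
0.678914
0.067579
0.289119
0.631288
-1.457156
-0.319671
-0.470373
-0.638878
-0.275142
1.494941
-0.865831
0.968278
-1.682870
-0.334885
0.162753
0.586222
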