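0.76895381576147592
0.80350476320821551
0.080118862391897541
0.77583411445899642
0.22563686653610021
0.14142428819778932
0.018825431866531087
0.15139776899753771
0.1920483764611105
0.98061723744760565
0.99528695746993789
0.96898788343480857
0.46932650193356046
0.03340769332790499
0.11265060313405177
0.10580599693938893
0.0032387984233185462
0.018417060381730681
0.27439634302358001
0.57914511923570144
0.39932188972483529
0.79172808183592536
0.57067311495818684
0.21969799951558905
0.14451109677821009
0.079190853686625179
0.021283010994719222
0.26609267184909074
0.093269360769065349
0.075013623513534147
0.10812263485734135
0.17147566701647199
0.089754422893401631
0.6307774430427483
0.21331475267671504
0.0071693148027354939
0.13618176903167459
0.021175048365625344
0.58247624560028655
0.55153759606515851
0.73073215532353297
0.24564640572659499
0.96969067130192022
0.25696705269764031
0.60177388702022883
0.0059013320564184528
0.31990095857183626
0.46204080371139017
0.24370448500304173
0.081656422421871544
0.46222826264780648
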