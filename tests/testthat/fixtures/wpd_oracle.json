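{"L1_a": [-0.8973478920241935, 0.01415191028169624, 0.03787111086317879, 0.10620114102824572, -0.37435994810787293, -1.293324619158088, -0.3336061524792396, -0.03374148107329513, 0.6770540692164801, 1.070877723436553, -0.4117904110460931, 0.010505396281285176, -0.1746615549808612, 0.3291364440416271, -0.1684712591745247, -0.01397958499349121, 0.2108805462701276, 1.8445534629100149, -0.17276191666144874, -0.3813213781269319, 1.0935296629471591, -1.3117957754725682, 0.8619903584699813, 0.14435280591491154, -0.05434700729348339, 0.6046424534528598, 0.7078838925925764, 0.6234321067951187, -0.34908317475269796, -0.7842483793126706, -0.6404644843273494, 0.7355009764288962, -0.5544256123748277, -0.6386166399126908, 0.8735837820743044], "L1_d": [0.5416021368469048, 0.9576242989098269, -1.8931963177248663, 1.2703909293909375, 0.037839408585223146, 0.9963776476053645, -0.8788150074292564, 0.01998128583786725, 1.1915082074123404, 1.050014883205296, -0.11303177415596959, 1.3896659414456536, -0.3025134564496789, 0.5636225112322054, -0.13660435702801535, 1.442118503903887, 0.09341790493058438, 0.6794656415138822, -0.7947193736336475, 0.05630978193810829, -0.185497061729887, -0.7675969382478093, 0.017044647489120504, 0.42735431652260947, 0.34822209538083726, 0.05987670130734303, -1.3573650827254315, 0.1709625303682678, -0.253419771658371, -1.885481672069971, -1.4153693139453367, 0.3478123303536895, -0.13002804888605027, 0.17273160372312799, 1.9902189921201912], "L2_aa": [-0.5596025652787348, 0.25396938340668407, -1.2071333561377056, -0.156174332328484, -0.043071823084695836, -1.3275519570763201, 0.36430951173181486, 0.6988339913991265, -0.1882929684013689, 0.10495649341331947, 0.10302981339239267, 1.050662920459679, 0.24924413531665965, -0.10055075032484562, 0.134227571593504, 0.861099194674666, 0.5414649251530411, -0.9622076805592313, -0.10525622672021537, 0.07575780265574411, 0.25895048415119437], "L2_ad": [-0.042628276724194114, -0.1509809463509357, -0.03338768261680734, 0.6257812125252394, 0.010569666872642231, -0.961433913790223, 0.030031423994095977, -0.3730926886890493, -0.20047141733222196, -1.2220274104710118, 1.6830620306870732, 1.240382964769755, -0.49059281374931407, 0.06759818246955279, -0.3844566320330873, -0.0036119675988108575, -0.8807469636795074, 0.98892922414474, -1.0582999518650877, 1.2581747335165747, -0.25809810366728453], "L2_dd": [-0.5286535644747565, -2.0856935380172, -0.7831253682052699, -1.1204861325855209, 0.7876451783479549, -1.1532572341271405, -0.9778540833182442, -0.5677210907582518, -0.9441479250951836, -0.7621653872863913, 0.11494116821717915, 0.3658731898393918, -0.17767349495181867, -0.9495508738248415, 0.19104946121747798, 0.0891593755495302, -0.6642681207326563, 0.9449515251235385, -1.1259938446906548, 1.0812200155648861, -0.5117796695758945], "L2_da": [0.9562925072567033, -0.6191651637176099, 1.3066257445405747, -0.42606136871616584, 0.661012122702725, -0.04292541064374147, 0.5822199192500566, 0.9690877024763492, 0.8266337046688002, 0.18342801251340612, 1.191756094569695, 0.011338459318395618, -0.2175708210280059, -0.7023832749996567, 0.7982257682250489, -0.7990744559027081, -0.02826547091472381, -2.234874482677772, -0.46810434850589, 1.2835373602349454, 1.8257955584664032], "L3_aaa": [-0.4872283686412651, -0.6485512631483037, -0.46805898226075837, -0.7328715819234266, -0.4336501667739422, -0.7179309242852618, 0.48415562907811577, 0.012817224597996883, 0.9643098484383813, -0.08908583044054774, 1.0427967896341799, -0.6684532502469697, 0.13123297414539492, 0.5190648487601839], "L3_aad": [-0.3277110698649945, -1.0269838204653754, 0.45330849761129177, 0.8693012258106204, -0.8415547739941347, -0.04329235485557493, -0.4774074132016168, 0.152266967851434, 0.014968265096164593, 0.6650514819765502, -0.1124000597259369, -0.05538412226740618, -0.6932447821637174, 0.24134776452322818], "L3_add": [0.05832479617525348, -0.08975250263452679, -0.19136194184861738, 0.83510413114793, 0.17303893081964264, 1.6565856640710634, -1.4186982150229983, 0.023298025940754565, -0.9054999910870398, -1.655184003615795, -0.7271897361693923, 1.4927601095198344, 1.4558990616414162, 0.46604775636033274], "L3_ada": [0.20891253008548755, 0.021827929622872513, -0.051842801456472354, -0.18301169420768507, 0.46245311258564054, -0.6134505001797844, -0.6454466833563589, 0.18859354672853545, 0.9953801185076392, -0.16004777602397935, -0.44348166306483777, -0.10594042083467026, 0.27387718600750705, 0.3712406672600639], "L3_dda": [-0.009105674437656364, -2.098306180103002, -0.9835194627800747, -2.284467766242994, -0.30979370258859157, -1.0909837615859441, -1.2114195002643808, -0.6907832946876127, 0.13766404276825409, -0.49678011953056717, -0.10522741272971423, -0.09073875155737518, 0.006111373760343597, 0.03356526653466718], "L3_ddd": [0.2997666009437056, 0.9033617933405871, 1.1906232349678947, -0.02223510824528533, -0.2600696813546603, 0.39836613732760245, -0.2849318752438547, 0.8270998446248063, -0.9504687285737256, -1.5758898528607022, -0.7472571949635762, 1.5129691351700534, 1.3735134764443384, 0.25735105750424864], "L3_dad": [0.4502273668210621, 1.5173641776016922, 0.6034446280609844, 0.1723604469933679, -0.06649165329916652, 0.9040732038403918, -0.0124538670686377, 1.2279907867631763, 0.8253606927073189, 0.6809747938706858, -0.31317302493780275, 0.12183931822565768, -0.9711293024923646, -0.802088875854865], "L3_daa": [0.34058109160424177, 0.2680268178757619, 0.9262597749704448, 0.49786751478380686, 0.3609010802395567, 0.35190633317306974, 1.120992742649709, 1.126846685355791, 0.0138673491276336, -0.11890819648530382, -0.17478721515085197, -2.1733503480163927, 1.582765069435969, 2.9310373295173084]}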