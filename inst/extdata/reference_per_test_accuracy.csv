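test_id,knn1,knn3,knn5,knn7,svm_linear,svm_rbf,naive_bayes,discriminant
1,42.5,35,27.5,27.5,47.5,25,52.5,37.5
2,57.5,67.5,70,70,62.5,62.5,60,70
3,40,42.5,60,55,27.5,50,50,47.5
4,67.5,70,75,67.5,60,65,65,62.5
5,67.5,57.5,60,65,67.5,67.5,67.5,65
6,62.5,67.5,67.5,72.5,62.5,72.5,72.5,65
7,52.5,60,57.5,55,67.5,67.5,70,50
8,57.5,62.5,62.5,70,65,67.5,65,62.5
9,47.5,62.5,65,50,60,50,55,57.5
10,62.5,62.5,65,55,55,55,57.5,55
11,42.5,60,72.5,72.5,75,72.5,70,72.5
12,50,45,42.5,57.5,65,65,65,65
13,40,45,57.5,57.5,52.5,60,60,45
14,52.5,60,55,55,50,60,45,55
15,57.5,60,62.5,65,72.5,72.5,65,72.5
16,50,55,62.5,65,72.5,72.5,65,72.5
17,60,57.5,57.5,65,72.5,60,72.5,67.5
18,45,45,55,65,67.5,67.5,65,67.5
19,40,37.5,45,35,40,40,22.5,42.5
20,52.5,55,55,47.5,60,62.5,65,62.5
21,47.5,40,40,27.5,45,55,52.5,52.5
22,42.5,35,52.5,52.5,67.5,55,55,65
23,47.5,55,55,47.5,62.5,60,60,50
24,35,35,22.5,35,42.5,42.5,37.5,50
25,62.5,62.5,67.5,67.5,62.5,67.5,65,62.5
26,55,62.5,57.5,62.5,57.5,57.5,55,55
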