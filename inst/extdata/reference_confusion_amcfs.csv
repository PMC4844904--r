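classifier,TP,FN,TN,FP
knn1,16,4,12,8
knn3,15,5,12,8
knn5,14,6,15,5
knn7,16,4,15,5
svm_linear,17,3,17,3
svm_rbf,18,2,17,3
naive_bayes,16,4,16,4
discriminant,16,4,17,3
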