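algorithm,tp_mean,tn_mean,fp_mean,fn_mean
logistic_regression,646.3,609.0,203.5,166.2
rbf_svm,606.3,520.3,292.2,206.2
gradient_boosted_trees,663.0,577.6,234.9,149.5
mlp,699.9,632.6,180.0,112.6
decision_tree,413.8,619.7,192.8,398.7
random_forest,630.3,499.0,313.5,182.2
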