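dataset,condition,precision,recall,f_score
diabetes,without_selection,90.8,90.2,90.5
breast_cancer,without_selection,89.9,85.6,87.7
heart_disease,without_selection,89.9,87.6,88.7
hepatitis,without_selection,90.4,88.1,89.2
diabetes,with_selection,95.5,94.4,94.9
breast_cancer,with_selection,96.3,94.1,95.2
heart_disease,with_selection,95.8,92.7,94.2
hepatitis,with_selection,96.6,95.1,95.8
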