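test_set,rater,class,accuracy,sensitivity,specificity,n
internal,pathologists,TA,89.8,76.1,95.5,157
internal,pathologists,TVA,94.3,88.2,95.8,157
internal,pathologists,HP,89.8,76.9,94.1,157
internal,pathologists,SSA,91.7,81.6,95.0,157
internal,model,TA,93.0,89.1,94.6,157
internal,model,TVA,95.5,97.1,95.1,157
internal,model,HP,92.4,82.1,95.8,157
internal,model,SSA,93.0,78.9,97.5,157
external,pathologists,TA,79.8,53.7,97.2,238
external,pathologists,TVA,81.5,100,77.7,238
external,pathologists,HP,91.6,80.8,96.8,238
external,pathologists,SSA,93.3,79.2,94.8,238
external,model,TA,84.5,73.7,91.6,238
external,model,TVA,89.5,97.6,87.8,238
external,model,HP,85.3,60.3,97.5,238
external,model,SSA,88.7,79.2,89.7,238
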