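metabolite,group0_median,group0_q1,group0_q3,group1_median,group1_q1,group1_q3
histidine,95.6,87.9,102.6,90.7,81.5,109.8
isoleucine,61.6,57.4,68.8,58.3,52.8,62.4
leucine,145,136,161,141,119,150
lysine,202,161,217,199,172,228
phenylalanine,74.8,68.9,87.3,73.2,61.6,88.0
methionine,26.8,23.6,28.2,25.3,19.7,27.1
threonine,117,99,140,107,95,123
tryptophan,64.3,59.0,68.3,53.0,45.8,61.3
valine,253,239,297,246,230,264
alanine,417,376,443,412,352,465
arginine,83.7,76.5,97.1,83.2,74.3,97.5
asparagine,47.8,45.0,52.2,46.1,42.1,50.4
aspartic-acid,25.6,20.6,35.3,20.5,17.1,29.0
cystine,56.4,49.1,65.7,56.2,50.9,66.8
glutamine,541,503,595,612,572,661
glycine,250,209,275,230,207,281
proline,192,171,221,179,168,196
tyrosine,70.7,65.5,84.1,62.3,53.9,75.9
sarcosine,1.7,1.4,2.1,1.2,1.0,1.5
serine,147,130,161,123,108,146
taurine,161,143,176,116,99,152
3-methylhistidine,12.2,7.0,22.2,14.1,7.9,29.1
beta-alanine,3.0,2.5,3.9,2.9,2.4,3.5
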