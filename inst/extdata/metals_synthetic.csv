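metal,covalent_index,essential,note
Pb,6.61,FALSE,synthetic illustrative value from standard covalent-index tabulations
Cd,2.71,FALSE,synthetic illustrative value from standard covalent-index tabulations
Cu,2.89,TRUE,synthetic illustrative value from standard covalent-index tabulations
Zn,2.04,TRUE,synthetic illustrative value from standard covalent-index tabulations
Fe,1.51,TRUE,synthetic illustrative value from standard covalent-index tabulations
Co,1.85,TRUE,synthetic illustrative value from standard covalent-index tabulations
Ni,2.22,TRUE,synthetic illustrative value from standard covalent-index tabulations
Hg,12.93,FALSE,synthetic illustrative value from standard covalent-index tabulations
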