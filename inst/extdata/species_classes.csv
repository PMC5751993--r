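species,ungulate,include
white-lipped peccary,TRUE,TRUE
collared peccary,TRUE,TRUE
lowland tapir,TRUE,TRUE
red brocket,TRUE,TRUE
brown brocket,TRUE,TRUE
paca,FALSE,TRUE
black agouti,FALSE,TRUE
armadillo,FALSE,TRUE
puma,FALSE,FALSE
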