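species,mass_kg
white-lipped peccary,32
collared peccary,21
lowland tapir,180
red brocket,30
brown brocket,16
paca,8
black agouti,4.5
armadillo,4
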