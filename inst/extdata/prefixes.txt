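di
ox
az
tri
iso
oxo
per
cyc
hex
pen
fluo
tetr
meth
chlo
brom
hydr
phen
amin
nitr
sulf
carb
cycl
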