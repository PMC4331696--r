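yl
ol
ic
al
ate
ide
ine
one
ene
ose
ium
oic
oate
azol
idin
ylic
onyl
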