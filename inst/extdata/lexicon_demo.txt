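aspirin
calcium
methanol
hydrogel
starch
hydroxyethyl starch
hydroxyethyl methacrylate
sodium trimetaphosphate
palytoxin
2-methoxyestradiol
polycalcium
acetoxyactinidine
methylergonovine
glucose
ethanol
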