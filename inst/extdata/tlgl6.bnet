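# T-LGL 6-node sub-network (mediator-eliminated core of the survival model).
# Node order defines the state bit order: S1P, FLIP, Fas, Ceramide, DISC,
# Apoptosis (leftmost digit = S1P). Fixed points: 000001 (normal) and
# 110000 (disease).
S1P* = NOT (Ceramide OR Apoptosis)
FLIP* = NOT (DISC OR Apoptosis)
Fas* = NOT (S1P OR Apoptosis)
Ceramide* = Fas AND NOT (S1P OR Apoptosis)
DISC* = (Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis
Apoptosis* = DISC OR Apoptosis
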