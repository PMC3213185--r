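# T-LGL 18-node sub-network: the nodes that do not stabilize under logical
# steady state analysis of the 60-node model with its six sources frozen
# (survival "AND NOT Apoptosis" clauses restored). TCR and CTLA4 form the
# oscillatory top sub-graph; the remaining 16 nodes form the bottom
# sub-graph with three fixed points.
CTLA4* = TCR AND NOT Apoptosis
TCR* = NOT CTLA4 AND NOT Apoptosis
S1P* = NOT Ceramide AND NOT Apoptosis
sFas* = S1P AND NOT Apoptosis
Fas* = NOT sFas AND NOT Apoptosis
Ceramide* = Fas AND NOT S1P AND NOT Apoptosis
DISC* = (Ceramide OR (Fas AND NOT FLIP)) AND NOT Apoptosis
Caspase* = ((BID AND NOT IAP) OR DISC) AND NOT Apoptosis
FLIP* = NOT DISC AND NOT Apoptosis
BID* = NOT MCL1 AND NOT Apoptosis
MCL1* = NOT DISC AND NOT Apoptosis
IAP* = NOT BID AND NOT Apoptosis
GPCR* = S1P AND NOT Apoptosis
SMAD* = GPCR AND NOT Apoptosis
CREB* = IFNG AND NOT Apoptosis
IFNG* = NOT (SMAD OR P2) AND NOT Apoptosis
P2* = (IFNG OR P2) AND NOT Apoptosis
Apoptosis* = Caspase OR Apoptosis
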