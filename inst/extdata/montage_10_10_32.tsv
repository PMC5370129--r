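label	x	y	z
Fp1	-0.2938926261	0.9045084972	0.3090169944
Fp2	0.2938926261	0.9045084972	0.3090169944
F7	-0.7694208843	0.5590169944	0.3090169944
F3	-0.4330274292	0.6454163629	0.6292256862
Fz	0	0.5877852523	0.8090169944
F4	0.4330274292	0.6454163629	0.6292256862
F8	0.7694208843	0.5590169944	0.3090169944
FC5	-0.7355608456	0.3029687252	0.6059374505
FC1	-0.3231239778	0.3231239778	0.8894840021
FC2	0.3231239778	0.3231239778	0.8894840021
FC6	0.7355608456	0.3029687252	0.6059374505
T7	-0.9510565163	0	0.3090169944
C3	-0.5877852523	0	0.8090169944
Cz	0	0	1
C4	0.5877852523	0	0.8090169944
T8	0.9510565163	0	0.3090169944
TP9	-0.9045084972	-0.2938926261	-0.3090169944
CP5	-0.7355608456	-0.3029687252	0.6059374505
CP1	-0.3231239778	-0.3231239778	0.8894840021
CP2	0.3231239778	-0.3231239778	0.8894840021
CP6	0.7355608456	-0.3029687252	0.6059374505
TP10	0.9045084972	-0.2938926261	-0.3090169944
P7	-0.7694208843	-0.5590169944	0.3090169944
P3	-0.4330274292	-0.6454163629	0.6292256862
Pz	0	-0.5877852523	0.8090169944
P4	0.4330274292	-0.6454163629	0.6292256862
P8	0.7694208843	-0.5590169944	0.3090169944
PO9	-0.5590169944	-0.7694208843	-0.3090169944
O1	-0.2938926261	-0.9045084972	0.3090169944
Oz	0	-0.9510565163	0.3090169944
O2	0.2938926261	-0.9045084972	0.3090169944
PO10	0.5590169944	-0.7694208843	-0.3090169944
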