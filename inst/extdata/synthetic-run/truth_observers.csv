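observer_id,route_id,effect
O0001,S01-R01,0.13112957668044137
O0002,S01-R02,0.06438505304078931
O0003,S01-R02,-0.1567677881760751
O0004,S01-R03,0.31514550395839547
O0005,S01-R03,0.1285798611434633
O0006,S02-R01,0.017952129319921135
O0007,S02-R01,0.0553101494582926
O0008,S02-R01,0.13585776321105417
O0009,S02-R02,0.01796657731581634
O0010,S02-R02,-0.598618016630587
O0011,S02-R02,0.05697659070613188
O0012,S02-R03,-0.07344692854819507
O0013,S02-R03,0.03704611297312187
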