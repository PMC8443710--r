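stratum_id,year,true_index
S01,2000,5.194500009086662
S01,2001,5.111595871813035
S01,2002,5.59590074154838
S01,2003,5.769132851817719
S01,2004,5.264381528928146
S01,2005,3.9408164688781304
S01,2006,4.378644302935793
S01,2007,4.226791906510053
S01,2008,3.3388257814846107
S01,2009,4.05033384618703
S02,2000,2.9858271453447216
S02,2001,2.7176713428016672
S02,2002,2.666373288387724
S02,2003,2.6214065286574275
S02,2004,3.249315174440407
S02,2005,2.4637833983952553
S02,2006,2.645789066087199
S02,2007,1.8654942945429744
S02,2008,2.7209476615593475
S02,2009,1.9554793189605064
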