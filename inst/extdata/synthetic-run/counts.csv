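route_id,stratum_id,year,day_of_year,observer_id,first_year,count,valid
S01-R01,S01,2000,178,O0001,1,9,1
S01-R01,S01,2001,163,O0001,0,11,1
S01-R01,S01,2002,187,O0001,0,5,1
S01-R01,S01,2003,189,O0001,0,3,1
S01-R01,S01,2004,155,O0001,0,4,1
S01-R01,S01,2005,178,O0001,0,3,1
S01-R01,S01,2006,186,O0001,0,2,1
S01-R01,S01,2007,172,O0001,0,10,1
S01-R01,S01,2008,174,O0001,0,4,1
S01-R01,S01,2009,188,O0001,0,2,1
S01-R02,S01,2000,184,O0002,1,3,1
S01-R02,S01,2001,171,O0002,0,11,1
S01-R02,S01,2002,182,O0003,1,3,1
S01-R02,S01,2003,150,O0003,0,6,1
S01-R02,S01,2004,180,O0003,0,7,1
S01-R02,S01,2005,173,O0003,0,8,1
S01-R02,S01,2006,151,O0003,0,3,1
S01-R02,S01,2007,148,O0003,0,3,1
S01-R02,S01,2008,166,O0003,0,1,1
S01-R02,S01,2009,180,O0003,0,2,1
S01-R03,S01,2000,178,O0004,1,6,1
S01-R03,S01,2001,182,O0004,0,11,1
S01-R03,S01,2002,152,O0004,0,5,1
S01-R03,S01,2003,188,O0004,0,10,1
S01-R03,S01,2004,158,O0004,0,8,1
S01-R03,S01,2005,151,O0004,0,10,1
S01-R03,S01,2006,178,O0004,0,8,1
S01-R03,S01,2007,159,O0004,0,0,1
S01-R03,S01,2008,180,O0004,0,2,1
S01-R03,S01,2009,163,O0005,1,3,1
S02-R01,S02,2000,176,O0006,1,3,1
S02-R01,S02,2001,180,O0006,0,2,1
S02-R01,S02,2002,153,O0006,0,3,1
S02-R01,S02,2003,146,O0006,0,2,1
S02-R01,S02,2004,151,O0006,0,5,1
S02-R01,S02,2005,176,O0006,0,1,1
S02-R01,S02,2006,188,O0007,1,2,1
S02-R01,S02,2007,170,O0007,0,0,1
S02-R01,S02,2008,172,O0007,0,5,1
S02-R01,S02,2009,154,O0008,1,1,1
S02-R02,S02,2000,169,O0009,1,0,1
S02-R02,S02,2001,153,O0009,0,1,1
S02-R02,S02,2002,165,O0009,0,7,1
S02-R02,S02,2003,159,O0009,0,2,1
S02-R02,S02,2004,150,O0009,0,5,1
S02-R02,S02,2005,153,O0009,0,5,1
S02-R02,S02,2006,178,O0009,0,2,1
S02-R02,S02,2007,163,O0009,0,2,1
S02-R02,S02,2008,164,O0010,1,0,1
S02-R02,S02,2009,167,O0011,1,0,1
S02-R03,S02,2000,164,O0012,1,3,1
S02-R03,S02,2001,151,O0012,0,2,1
S02-R03,S02,2002,182,O0012,0,3,1
S02-R03,S02,2003,172,O0013,1,6,1
S02-R03,S02,2004,181,O0013,0,3,1
S02-R03,S02,2005,180,O0013,0,2,1
S02-R03,S02,2006,187,O0013,0,3,1
S02-R03,S02,2007,184,O0013,0,2,1
S02-R03,S02,2008,159,O0013,0,2,1
S02-R03,S02,2009,156,O0013,0,5,1
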