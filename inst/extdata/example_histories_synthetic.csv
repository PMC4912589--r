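id,cohort_year,y1,y2,y3,y4,y5,y6,y7,y8,y9,y10,y11,y12
g0001,1,1,0,0,0,0,0,0,0,0,0,0,0
g0002,1,1,0,0,0,0,0,0,0,0,0,0,0
g0003,1,1,0,2,0,0,0,0,0,0,0,0,0
g0004,1,1,0,0,0,0,0,0,0,0,0,0,0
g0005,1,1,1,0,0,0,0,0,0,0,0,0,0
g0006,1,1,2,0,0,0,0,0,0,0,0,0,0
g0007,1,1,0,0,0,0,0,0,0,0,0,0,0
g0008,1,1,2,0,0,0,0,0,0,0,0,0,0
g0009,1,1,1,0,0,0,0,0,0,0,0,0,0
g0010,1,1,0,0,0,0,0,0,0,0,0,0,0
g0011,1,1,1,0,3,0,0,0,0,0,0,0,0
g0012,1,1,0,0,0,0,0,0,0,0,0,0,0
g0013,1,1,0,0,0,0,0,0,0,0,0,0,0
g0014,1,1,1,0,0,0,0,0,0,0,0,0,0
g0015,1,1,0,2,2,4,0,0,0,0,0,0,0
g0016,1,1,0,0,0,0,0,0,0,0,0,0,0
g0017,1,1,0,0,0,0,0,0,0,0,0,0,0
g0018,1,1,1,1,1,1,1,1,1,2,3,0,0
g0019,1,1,3,3,0,3,0,3,0,3,3,0,3
g0020,1,1,3,3,3,0,3,0,0,0,0,0,0
g0021,3,0,0,1,3,0,0,0,0,0,0,0,0
g0022,3,0,0,1,0,0,0,0,0,0,0,0,0
g0023,3,0,0,1,3,0,0,0,0,0,0,0,0
g0024,3,0,0,1,1,0,0,0,0,0,0,0,0
g0025,3,0,0,1,1,1,3,4,4,4,4,4,4
g0026,3,0,0,1,1,0,0,0,0,0,0,0,0
g0027,3,0,0,1,0,0,0,0,0,0,0,0,0
g0028,3,0,0,1,0,0,3,0,0,0,0,0,0
g0029,3,0,0,1,3,0,0,0,0,0,0,0,0
g0030,3,0,0,1,0,0,0,3,3,3,3,3,0
g0031,3,0,0,1,0,0,0,0,0,0,0,0,0
g0032,3,0,0,1,0,0,0,0,0,0,0,0,0
g0033,3,0,0,1,1,0,1,1,0,3,4,4,0
g0034,3,0,0,1,3,0,0,0,0,0,0,0,0
g0035,3,0,0,1,0,0,0,0,0,0,0,0,0
g0036,3,0,0,1,0,3,3,3,0,0,0,0,0
g0037,3,0,0,1,1,3,3,3,3,0,0,0,0
g0038,3,0,0,1,1,1,0,1,1,1,0,0,0
g0039,3,0,0,1,1,1,1,0,0,3,0,0,3
g0040,3,0,0,1,0,0,0,0,0,0,0,0,0
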