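compound,col1,col2,col3,col4,col5,col6,col7,col8,col9,col10,col11,col12,col13,col14,col15,col16,col17,col18,col19,col20,col21,col22,col23,col24,col25,col26,col27,col28,col29,col30
Chonglou saponin VII,0.021,0.010,0.004,0.011,0.009,0.012,0.018,0.008,0.006,0.008,0.015,0.014,0.012,0.022,0.013,0.006,0.013,0.010,0.013,0.006,0.015,0.021,0.007,0.016,0.017,0.007,0.247,0.003,0.007,0.012
Chonglou saponin VI,0.006,0.006,0.027,0.018,0.004,0.016,0.008,0.023,0.005,0.021,0.016,0.007,0.004,0.003,0.024,0.018,0.006,0.022,0.010,0.021,0.010,0.005,0.008,0.004,0.018,0.014,0.250,0.005,0.011,0.017
Chonglou saponin II,0.007,0.011,0.021,0.032,0.017,0.006,0.011,0.016,0.013,0.011,0.023,0.003,0.006,0.009,0.010,0.004,0.019,0.007,0.006,0.008,0.008,0.020,0.011,0.019,0.004,0.002,0.344,0.003,0.031,0.011
Chonglou saponin I,0.004,0.002,0.006,0.036,0.003,0.007,0.003,0.011,0.005,0.004,0.010,0.015,0.001,0.005,0.006,0.010,0.011,0.005,0.005,0.004,0.007,0.023,0.004,0.009,0.021,0.001,0.330,0.002,0.007,0.014
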