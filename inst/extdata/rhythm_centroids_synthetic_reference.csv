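rhythm_id,click_count,s1,s2,s3,s4,s5,s6,s7,s8,s9
ref01,3,0.5,0.5,,,,,,,
ref02,4,0.333333333333333,0.333333333333333,0.333333333333333,,,,,,
ref03,5,0.25,0.25,0.25,0.25,,,,,
ref04,6,0.2,0.2,0.2,0.2,0.2,,,,
ref05,7,0.166666666666667,0.166666666666667,0.166666666666667,0.166666666666667,0.166666666666667,0.166666666666667,,,
ref06,8,0.142857142857143,0.142857142857143,0.142857142857143,0.142857142857143,0.142857142857143,0.142857142857143,0.142857142857143,,
ref07,9,0.125,0.125,0.125,0.125,0.125,0.125,0.125,0.125,
ref08,10,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111
ref09,4,0.5,0.25,0.25,,,,,,
ref10,5,0.4,0.2,0.2,0.2,,,,,
ref11,6,0.333333333333333,0.166666666666667,0.166666666666667,0.166666666666667,0.166666666666667,,,,
ref12,7,0.285714285714286,0.142857142857143,0.142857142857143,0.142857142857143,0.142857142857143,0.142857142857143,,,
ref13,8,0.25,0.125,0.125,0.125,0.125,0.125,0.125,,
ref14,9,0.222222222222222,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,0.111111111111111,
ref15,10,0.2,0.1,0.1,0.1,0.1,0.1,0.1,0.1,0.1
ref16,5,0.333333333333333,0.333333333333333,0.166666666666667,0.166666666666667,,,,,
ref17,6,0.285714285714286,0.285714285714286,0.142857142857143,0.142857142857143,0.142857142857143,,,,
ref18,7,0.25,0.25,0.125,0.125,0.125,0.125,,,
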