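object,role,essi,sci,swi,sti,ope,ropi
SEER 17,reference,1.000,1.000,1.000,1.000,1.000,1.000
Iowa,benchmark,0.951,0.993,1.032,1.023,1.048,1.110
New Mexico,benchmark,0.973,0.959,1.023,1.037,1.017,1.090
Seattle (Puget Sound),benchmark,0.960,1.035,1.033,1.004,1.074,1.080
New Jersey,benchmark,0.991,0.938,0.997,1.052,0.983,1.059
Utah,benchmark,0.991,0.987,1.026,1.010,1.022,1.045
San Francisco-Oakland (SF),benchmark,1.002,1.036,1.039,0.987,1.062,1.023
San Jose-Monterey (SJM),benchmark,0.983,1.049,1.009,0.991,1.049,1.018
Conneticut,benchmark,0.973,1.020,0.985,1.000,1.005,1.013
California excl. SF/SJM/LA,benchmark,0.994,1.018,1.006,0.990,1.014,1.002
Alaska Natives,benchmark,0.981,0.932,0.956,0.980,0.874,0.955
Atlanta,benchmark,1.024,1.001,0.982,0.982,0.965,0.941
Los Angeles (LA),benchmark,1.051,1.018,1.008,0.978,1.003,0.938
Kentucky,benchmark,0.965,0.927,0.862,1.045,0.834,0.933
Detroit (Metropolitan),benchmark,1.029,0.981,0.935,0.995,0.913,0.905
Hawaii,benchmark,0.975,1.078,0.926,0.948,0.947,0.900
Lousiana,benchmark,1.074,0.960,0.952,0.975,0.891,0.865
Rural Georgia,benchmark,0.947,0.884,0.709,1.076,0.674,0.805
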