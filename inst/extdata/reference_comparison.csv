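response,criterion1,criterion2,criterion3,experimental,published_error
Comp_bulgeA,0.266,0.262,0.269,0.50,0.469
Comp_bulgeL,0.096,0.090,0.095,0.35,0.732
Comp_bulgeP,0.624,0.602,0.625,0.75,0.177
Comp_stiff,915.640,944.360,922.740,810,0.125
Shear_stiff,302.925,304.920,299.090,300,0.010
Exte_bulgeL,0.106,0.099,0.106,0.10,0.041
Exte_bulgeP,0.527,0.559,0.538,0.24,0.539
Exte_stiff,1.634,1.678,1.645,1.53,0.073
LBend_bulgeL,0.997,0.871,0.977,2.11,0.551
LBend_bulgeP,1.282,1.173,1.263,1.13,0.085
LBend_stiff,1.489,2.175,1.493,2.00,0.183
Flex_bulgeL,0.077,0.080,0.076,0.07,0.096
Flex_bulgeP,0.380,0.373,0.373,0.73,0.486
Flex_stiff,1.488,1.524,1.500,1.18,0.213
Tors_stiff,3.550,3.549,3.506,2.10,0.404
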