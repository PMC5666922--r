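variable,role,goal,target,value,desirability
C10,input,in_range,0.125,0.102,1.000
C0,input,in_range,0.03,0.015,1.000
Fiber12,input,in_range,532.5,518.133,1.000
Fiber34,input,in_range,509,500.083,1.000
Fiber56,input,in_range,479,517.692,1.000
Fiber78,input,in_range,431.5,463.054,1.000
Fiber910,input,in_range,384,366.794,1.000
Annulus_E,input,in_range,4.1,3.951,1.000
Annulus_mu,input,in_range,0.35,0.201,1.000
Cartil_E,input,in_range,39,42.121,1.000
Cartil_mu,input,in_range,0.35,0.430,1.000
Comp_bulgeA,output,target,0.5,0.265,0.262
Comp_bulgeL,output,target,0.35,0.097,0.244
Comp_bulgeP,output,target,0.75,0.650,0.651
Comp_stiff,output,target,810,826.143,0.983
Shear_stiff,output,target,300,298.124,0.964
Exte_bulgeL,output,target,0.1,0.100,1.000
Exte_bulgeP,output,target,0.24,0.490,0.711
Exte_stiff,output,target,1.53,2.167,0.867
LBend_bulgeL,output,target,2.11,1.235,0.534
LBend_bulgeP,output,target,1.13,1.459,0.792
LBend_stiff,output,target,2,1.465,0.634
Flex_bulgeL,output,target,0.07,0.074,0.873
Flex_bulgeP,output,target,0.73,0.375,0.381
Flex_stiff,output,target,1.18,1.357,0.880
Tors_stiff,output,target,2.1,3.401,0.451
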