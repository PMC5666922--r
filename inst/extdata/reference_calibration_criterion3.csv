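variable,role,goal,target,value,desirability
C10,input,in_range,0.125,0.102,1.000
C0,input,in_range,0.03,0.015,1.000
Fiber12,input,in_range,532.5,559.341,1.000
Fiber34,input,in_range,509,512.790,1.000
Fiber56,input,in_range,479,443.243,1.000
Fiber78,input,in_range,431.5,396.348,1.000
Fiber910,input,in_range,384,348.282,1.000
Annulus_E,input,in_range,4.1,3.951,1.000
Annulus_mu,input,in_range,0.35,0.214,1.000
Cartil_E,input,in_range,39,36.933,1.000
Cartil_mu,input,in_range,0.35,0.429,1.000
Comp_bulgeA,output,target,0.5,0.277,0.298
Comp_bulgeL,output,target,0.35,0.101,0.257
Comp_bulgeP,output,target,0.75,0.673,0.730
Comp_stiff,output,in_range,810,821.981,1.000
Shear_stiff,output,in_range,300,287.011,1.000
Exte_bulgeL,output,target,0.1,0.103,0.947
Exte_bulgeP,output,target,0.24,0.481,0.722
Exte_stiff,output,in_range,1.53,2.403,1.000
LBend_bulgeL,output,target,2.11,1.314,0.576
LBend_bulgeP,output,target,1.13,1.595,0.706
LBend_stiff,output,in_range,2,1.288,1.000
Flex_bulgeL,output,target,0.07,0.075,0.846
Flex_bulgeP,output,target,0.73,0.373,0.378
Flex_stiff,output,in_range,1.18,1.315,1.000
Tors_stiff,output,in_range,2.1,3.311,1.000
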