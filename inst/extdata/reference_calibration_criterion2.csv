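variable,role,goal,target,value,desirability
C10,input,in_range,0.125,0.105,1.000
C0,input,in_range,0.03,0.015,1.000
Fiber12,input,in_range,532.5,541.867,1.000
Fiber34,input,in_range,509,500.123,1.000
Fiber56,input,in_range,479,458.643,1.000
Fiber78,input,in_range,431.5,396.291,1.000
Fiber910,input,in_range,384,421.320,1.000
Annulus_E,input,in_range,4.1,3.952205,1.000
Annulus_mu,input,in_range,0.35,0.2269,1.000
Cartil_E,input,in_range,39,45.575,1.000
Cartil_mu,input,in_range,0.35,0.2756,1.000
Comp_bulgeA,output,in_range,0.5,0.262,1.000
Comp_bulgeL,output,in_range,0.35,0.089,1.000
Comp_bulgeP,output,in_range,0.75,0.628,1.000
Comp_stiff,output,target,810,900.147,0.907
Shear_stiff,output,target,300,300.000,1.000
Exte_bulgeL,output,in_range,0.1,0.105,1.000
Exte_bulgeP,output,in_range,0.24,0.605,1.000
Exte_stiff,output,target,1.53,1.530,0.999
LBend_bulgeL,output,in_range,2.11,0.895,1.000
LBend_bulgeP,output,in_range,1.13,1.270,1.000
LBend_stiff,output,target,2,1.984,0.989
Flex_bulgeL,output,in_range,0.07,0.076,1.000
Flex_bulgeP,output,in_range,0.73,0.363,1.000
Flex_stiff,output,target,1.18,1.518,0.772
Tors_stiff,output,target,2.1,3.456,0.428
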