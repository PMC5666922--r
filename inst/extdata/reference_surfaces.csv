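response,term,coefficient
Comp_bulgeA,(Intercept),0.453125
Comp_bulgeA,C10,-0.150922
Comp_bulgeA,C0,-0.154598
Comp_bulgeA,Fiber12,-0.000044
Comp_bulgeA,Fiber56,-0.000028
Comp_bulgeA,Fiber78,-0.000023
Comp_bulgeA,Fiber910,-0.000025
Comp_bulgeA,Annulus_E,-0.034134
Comp_bulgeA,Annulus_mu,0.262148
Comp_bulgeA,Cartil_E,-0.001137
Comp_bulgeA,Cartil_mu,0.040998
Comp_bulgeL,(Intercept),0.169454
Comp_bulgeL,C10,-0.084948
Comp_bulgeL,C0,-0.087169
Comp_bulgeL,Fiber12,-0.00005
Comp_bulgeL,Annulus_E,-0.006264
Comp_bulgeL,Annulus_mu,0.088348
Comp_bulgeL,Cartil_E,-0.001015
Comp_bulgeL,Cartil_mu,0.031074
Comp_bulgeP,(Intercept),1.206599
Comp_bulgeP,C10,-0.91178
Comp_bulgeP,C0,-0.915255
Comp_bulgeP,Annulus_E,-0.113434
Comp_bulgeP,Annulus_mu,0.442496
Comp_bulgeP,Cartil_E,-0.003303
Comp_bulgeP,Cartil_mu,0.117189
Comp_stiff,(Intercept),-635.243327
Comp_stiff,C10,822.048324
Comp_stiff,C0,834.364625
Comp_stiff,Annulus_E,180.06106
Comp_stiff,Annulus_mu,2051.947822
Comp_stiff,Cartil_E,5.673156
Shear_stiff,(Intercept),-70.312808
Shear_stiff,C10,199.672441
Shear_stiff,C0,199.736145
Shear_stiff,Fiber12,0.02166
Shear_stiff,Fiber34,0.055155
Shear_stiff,Fiber56,0.031639
Shear_stiff,Fiber78,0.057449
Shear_stiff,Fiber910,0.044255
Shear_stiff,Annulus_E,58.151336
Shear_stiff,Annulus_mu,-72.981833
Shear_stiff,Cartil_E,0.926751
Shear_stiff,Cartil_mu,-16.717294
Exte_bulgeL,(Intercept),0.083398
Exte_bulgeL,Fiber910,0.00016
Exte_bulgeL,Annulus_mu,0.028063
Exte_bulgeL,Cartil_E,-0.001135
Exte_bulgeP,(Intercept),-0.243941
Exte_bulgeP,Fiber910,0.001987
Exte_bulgeP,Annulus_mu,0.76198
Exte_bulgeP,Cartil_E,-0.003522
Exte_stiff,(Intercept),6.205107
Exte_stiff,Fiber910,-0.01339
Exte_stiff,Annulus_mu,2.595841
Exte_stiff,Cartil_E,0.008305
LBend_bulgeL,(Intercept),1.574761
LBend_bulgeL,C10,-1.014308
LBend_bulgeL,Annulus_mu,-0.929876
LBend_bulgeL,Cartil_E,-0.017706
LBend_bulgeL,Cartil_mu,1.620387
LBend_bulgeP,(Intercept),2.995354
LBend_bulgeP,C10,-3.019289
LBend_bulgeP,C0,-3.118902
LBend_bulgeP,Annulus_E,-0.212027
LBend_bulgeP,Annulus_mu,1.351171
LBend_bulgeP,Cartil_E,-0.023247
LBend_bulgeP,Cartil_mu,0.84824
LBend_stiff,(Intercept),-1.428516
LBend_stiff,C10,1.708987
LBend_stiff,Annulus_E,0.297374
LBend_stiff,Annulus_mu,3.014858
LBend_stiff,Cartil_E,0.041594
LBend_stiff,Cartil_mu,-1.896308
Flex_bulgeL,(Intercept),0.125918
Flex_bulgeL,C10,-0.064104
Flex_bulgeL,C0,-0.060597
Flex_bulgeL,Fiber12,-0.000031
Flex_bulgeL,Annulus_E,-0.00418
Flex_bulgeL,Annulus_mu,0.04945
Flex_bulgeL,Cartil_E,-0.000311
Flex_bulgeL,Cartil_mu,-0.019064
Flex_bulgeP,(Intercept),0.681909
Flex_bulgeP,C10,-0.920479
Flex_bulgeP,C0,-0.921496
Flex_bulgeP,Annulus_E,-0.048626
Flex_bulgeP,Annulus_mu,-0.113105
Flex_bulgeP,Cartil_mu,0.039252
Flex_stiff,(Intercept),-0.697824
Flex_stiff,C10,1.433372
Flex_stiff,C0,1.443693
Flex_stiff,Annulus_E,0.269714
Flex_stiff,Annulus_mu,2.099688
Flex_stiff,Cartil_E,0.013196
Flex_stiff,Cartil_mu,-0.368862
Tors_stiff,(Intercept),-2.079685
Tors_stiff,C10,1.056596
Tors_stiff,C0,0.901329
Tors_stiff,Fiber34,0.00263
Tors_stiff,Fiber56,-0.000469
Tors_stiff,Fiber78,0.001202
Tors_stiff,Annulus_E,0.908448
Tors_stiff,Annulus_mu,-0.905043
Tors_stiff,Cartil_E,0.013001
Tors_stiff,Cartil_mu,-0.521362
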