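# Default disc-model configuration: geometry and boundary-condition areas,
# standard-test loads, experimental stiffness/bulge targets, and the design
# ranges of the eleven material parameters.
geometry:
  width: 50.0          # mm
  depth: 35.0          # mm
  height: 10.0         # mm
  support_area: 1440.0 # mm^2, upper steel support
  anterior_area: 745.0 # mm^2, flexion pressure patch
  half_area: 720.0     # mm^2, lateral-bending pressure patch
  torsion_radius: 25.0 # mm, half the disc width
loads:
- {test: compression,    load: 500.0,  unit: "N"}
- {test: flexion,        load: 5.0,    unit: N.m}
- {test: extension,      load: 4.0,    unit: N.m}
- {test: lateral_bending, load: 10.6,  unit: N.m}
- {test: shear,          load: 450.0,  unit: "N"}
- {test: torsion,        load: 10.0,   unit: N.m}
targets:
- {response: Comp_bulgeA,  class: bulge,     test: compression,     units: mm,       target: 0.5}
- {response: Comp_bulgeL,  class: bulge,     test: compression,     units: mm,       target: 0.35}
- {response: Comp_bulgeP,  class: bulge,     test: compression,     units: mm,       target: 0.75}
- {response: Comp_stiff,   class: stiffness, test: compression,     units: N/mm,     target: 810.0}
- {response: Shear_stiff,  class: stiffness, test: shear,           units: N/mm,     target: 300.0}
- {response: Exte_bulgeL,  class: bulge,     test: extension,       units: mm,       target: 0.1}
- {response: Exte_bulgeP,  class: bulge,     test: extension,       units: mm,       target: 0.24}
- {response: Exte_stiff,   class: stiffness, test: extension,       units: N.m/deg,  target: 1.53}
- {response: LBend_bulgeL, class: bulge,     test: lateral_bending, units: mm,       target: 2.11}
- {response: LBend_bulgeP, class: bulge,     test: lateral_bending, units: mm,       target: 1.13}
- {response: LBend_stiff,  class: stiffness, test: lateral_bending, units: N.m/deg,  target: 2.0}
- {response: Flex_bulgeL,  class: bulge,     test: flexion,         units: mm,       target: 0.07}
- {response: Flex_bulgeP,  class: bulge,     test: flexion,         units: mm,       target: 0.73}
- {response: Flex_stiff,   class: stiffness, test: flexion,         units: N.m/deg,  target: 1.18}
- {response: Tors_stiff,   class: stiffness, test: torsion,         units: N.m/deg,  target: 2.1}
ranges:
- {parameter: C10,        min: 0.11,  max: 0.14}
- {parameter: C0,         min: 0.02,  max: 0.04}
- {parameter: Fiber12,    min: 515.0, max: 550.0}
- {parameter: Fiber34,    min: 503.0, max: 515.0}
- {parameter: Fiber56,    min: 455.0, max: 503.0}
- {parameter: Fiber78,    min: 408.0, max: 455.0}
- {parameter: Fiber910,   min: 360.0, max: 408.0}
- {parameter: Annulus_E,  min: 4.0,   max: 4.2}
- {parameter: Annulus_mu, min: 0.25,  max: 0.45}
- {parameter: Cartil_E,   min: 23.0,  max: 55.0}
- {parameter: Cartil_mu,  min: 0.3,   max: 0.4}
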