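# Input parameter set, 1% guar-gum formulation.
# Fields not listed in the source table for this formulation are shared
# with the control set (saturation pressure, oven humidity, geometry,
# emissivity, transfer coefficients, air properties).
formulation: guar
P_sat: 98000
RH: 10
T0: 293
W0: 0.62
r: 0.061
rho: 421
rho_s: 341
epsilon: 0.9
delta_const: 1
h: 10
lambda_v_ref: 2.33e+06
D: 1.2e-04
nu: 2.886e-05
alpha: 1.17e-07
Cp_meas: 1640
k: 0.28
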