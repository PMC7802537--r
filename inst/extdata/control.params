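# Input parameter set, control formulation (no hydrocolloid).
# All values in SI units; temperatures kelvin; moisture dry basis.
formulation: control
P_sat: 98000          # water vapour saturation pressure reference, Pa
RH: 10                # oven ambient relative humidity, %
T0: 293               # initial dough temperature, K
W0: 0.58              # initial moisture content, kg water / kg dry solid
r: 0.061              # loaf radius (infinite-cylinder geometry), m
rho: 402              # initial dough density, kg/m^3
rho_s: 315            # solid-matrix density, kg/m^3
epsilon: 0.9          # surface emissivity
delta_const: 1        # delta-type function value (literal evaporation mode)
h: 10                 # surface heat-transfer coefficient, W/m^2 K
lambda_v_ref: 2.33e+06   # latent heat of evaporation reference, J/kg
D: 1.2e-04            # effective water diffusion coefficient, m^2/s
nu: 2.886e-05         # kinematic viscosity of air, m^2/s
alpha: 1.17e-07       # thermal diffusivity of air, m^2/s
Cp_meas: 2489         # measured specific heat of bread, J/kg K
k: 0.18               # bread thermal conductivity, W/m K
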