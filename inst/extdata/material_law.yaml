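# Default material-law constants: Lotz density conversion and the
# three-branch density -> Young's modulus mapping.
lotz_slope: 0.0012
lotz_intercept: 0.17
air_modulus: 1.0
trab_coefficient: 11417.6
trab_exponent: 1.89
cortical_modulus: 17000.0
cutoff_density: 1.0
modulus_floor: 1.0
transverse_factor: 1.28
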