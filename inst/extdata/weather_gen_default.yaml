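# Default synthetic weather regime (Podgorica-like Mediterranean fixture).
lat: 42.44
t_annual_mean: 15
t_annual_amplitude: 10
t_diurnal_range: 10
t_noise_sd: 2
t_ar1: 0.7
p_wet_given_wet: 0.55
p_wet_given_dry: 0.25
precip_gamma_shape: 0.9
precip_gamma_scale: 12
rh_base: 65
seed: 1
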