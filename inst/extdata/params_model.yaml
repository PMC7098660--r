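gamma_R: 0.45
alpha: 0.666666666666667
gamma_w: 0.15
l_w: 0.06
beta_w: 1.9157
gamma_Att: 0.12
l_Att: 0.2
d_Att: 0.03
beta_Att: 1.395
lambda_Att: 0.9326
gamma_Ali: 0.09
l_Ali: 0.2
d_Ali: 0.06
beta_Ali: 0.9012
lambda_Ali: 1.6385
v0: 0.14
tau0: 0.8
mean_kick_length: 0.07
arena_radius: 0.25
d_cut: infinite
kick_law: gamma
kick_shape: 4.0
tau_mode: from_length
tau_mean: 0.5
noise_convention: boundary
boundary_rejection: length_first
preset: model
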