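gamma_R: 0.1
alpha: 1.0
gamma_w: 0.79
l_w: 0.11
beta_w: 1.9157
gamma_Att: 0.18
l_Att: 0.37
d_Att: 0.18
beta_Att: 1.395
lambda_Att: 0.9326
gamma_Ali: 0.04
l_Ali: 0.37
d_Ali: 0.05
beta_Ali: 0.9012
lambda_Ali: 1.6385
v0: 0.0375
tau0: 0.9
mean_kick_length: 0.074
arena_radius: 0.42
d_cut: infinite
kick_law: constant
kick_shape: 4.0
tau_mode: constant
tau_mean: 1.3
noise_convention: boundary
boundary_rejection: length_first
preset: robots
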