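# Shared parameter sets: the two worked operating points (high-density and
# symmetric shock) plus a low-density mirror.
hd_params <- function(N = 500) {
  scaled_model_params(alpha = 0.45, gamma = 0.66, Omega = 0.2, r = 0, N = N)
}
shock_params <- function(N = 500) {
  scaled_model_params(alpha = 0.3, gamma = 0.7, Omega = 0.2, r = 0, N = N)
}
ld_params <- function(N = 500) {
  scaled_model_params(alpha = 0.1, gamma = 0.7, Omega = 0.2, r = 0, N = N)
}

random_rate_params <- function(N) {
  model_params(alpha = runif(1, 0.05, 0.95), beta = runif(1, 0.05, 0.95),
               omega_a = runif(1, 0, 0.1), omega_d = runif(1, 0, 0.1), N = N)
}
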