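# Baseline parameter sets used throughout the suite: the coexistence
# regime alpha = 0.5, r = 1.4, gamma = 1.2, uncontrolled and with the
# reference PD gains.
base_params <- function(tau = NULL, kp = 0, kd = 0) {
  ma_params(alpha = 0.5, r = 1.4, gamma = 1.2, kp = kp, kd = kd, tau = tau)
}

# case 1: self-diffusion only; case 2: cross-diffusion only
case1_diffusion <- function(d_a2 = 1, n = 100L) {
  ma_diffusion(d_m1 = 0.8, d_m2 = 0, d_a1 = 0, d_a2 = d_a2,
               delta = 10, n = n)
}
case2_diffusion <- function(n = 100L) {
  ma_diffusion(d_m1 = 0, d_m2 = 0.6, d_a1 = 0.3, d_a2 = 0,
               delta = 20, n = n)
}

with_tau_set <- function(p, tau) {
  p$tau <- tau
  p
}

# random parameter set satisfying the coexistence condition C2
# (0 < alpha < 1/r < 1), optionally with random gains
random_c2_params <- function(with_gains = TRUE, tau = NULL) {
  r <- runif(1, 1.05, 3)
  alpha <- runif(1, 0.05, 0.95) / r
  gamma <- runif(1, 0.2, 3)
  kp <- if (with_gains) runif(1, -0.5, 0.5) else 0
  kd <- if (with_gains) runif(1, -0.9, 0.9) else 0
  ma_params(alpha = alpha, r = r, gamma = gamma, kp = kp, kd = kd, tau = tau)
}
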