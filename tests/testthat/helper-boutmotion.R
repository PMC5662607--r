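# Shared helpers for the test suite.

# unit-parameter model (eta = 1, zeta = gamma)
unit_params <- function(gamma = 1, accel_dist = "gaussian") {
  model_params(nu_a2 = 1, omega = 1, gamma = gamma, accel_dist = accel_dist)
}

# the drag grid used throughout the reference figures: zeta = 4^n, n = -3..3
zeta_grid_4n <- 4^(-3:3)

# sample skewness and excess kurtosis
sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
sample_excess_kurtosis <- function(x) mean((x - mean(x))^4) / sd(x)^4 - 3

# standard error of the sample skewness under normality
se_skewness <- function(n) sqrt(6 / n)
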