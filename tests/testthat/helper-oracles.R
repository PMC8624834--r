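# Shared helpers: independent oracles and random-case generators.

# classic dimer toggle (no leakiness, no resources): the textbook field
classic_rhs <- function(y, z, alpha) {
  c(alpha / (1 + z^2) - y, alpha / (1 + y^2) - z)
}

# primed-formulation field: basal and regulated production share unit weight
primed_rhs <- function(y, z, alpha_p, beta_p, nu_p, beta_c = 0) {
  g <- function(v) nu_p + (1 - nu_p) / (1 + v^2)
  denom <- 1 + beta_p * (g(y) + g(z)) + beta_c
  c(alpha_p * g(z) / denom - y, alpha_p * g(y) / denom - z)
}

random_params <- function(n, alpha = c(0.5, 60), beta = c(0, 10),
                          nu = c(0, 0.3), beta_c = c(0, 4)) {
  data.frame(alpha = runif(n, alpha[1], alpha[2]),
             beta = runif(n, beta[1], beta[2]),
             nu = runif(n, nu[1], nu[2]),
             beta_c = runif(n, beta_c[1], beta_c[2]))
}

random_states <- function(n, top = 20) {
  cbind(runif(n, 0, top), runif(n, 0, top))
}
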