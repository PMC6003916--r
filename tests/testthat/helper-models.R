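# Draw random model parameter sets on the unit cube (r_h = 1). gamma_max
# keeps the linear Bellman solve applicable where a test needs it.
random_models <- function(n, seed, gamma_max = 0.999) {
  set.seed(seed)
  data.frame(
    delta = runif(n), rho = runif(n), gamma = runif(n, 0, gamma_max),
    r_l = runif(n), r_min = runif(n)
  )
}

model_from_row <- function(row) {
  tipping_model(delta = row$delta, rho = row$rho, gamma = row$gamma,
                r_l = row$r_l, r_min = row$r_min)
}
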