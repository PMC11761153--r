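# Random valid parameter draws used by property-style tests. Mortalities
# are kept strictly positive so the adult balance c4*c5 - beta_1*beta_2 =
# mu_s*c5 + beta_1*mu_g stays positive and every draw is a valid model.
random_locust_params <- function(n, seed) {
  rng <- parameter_ranges()
  rng <- rng[!rng$fixed, ]
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      draw <- stats::runif(nrow(rng), rng$low, rng$high)
      names(draw) <- rng$parameter
      locust_params(as.list(draw))
    })
  })
}

baseline_constants <- function() {
  locust_params()[c("theta", "beta_1", "beta_2", "psi", "eta", "K")]
}
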