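# Small studies built in code for unit tests.

toy_study <- function(value = c(0, 1, 2), u = c(0.1, 0.1, 0.1),
                      dof = Inf, include = TRUE, labs = NULL) {
  n <- length(value)
  kc_study(tibble::tibble(
    lab = labs %||% paste0("L", seq_len(n)),
    value = value,
    u = rep_len(u, n),
    dof = rep_len(dof, n),
    include = rep_len(include, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fast MCMC settings for tests that only need a roughly correct posterior
test_mcmc <- function(seed = 1) {
  mcmc_control(chains = 2, warmup = 1000, samples = 1000, thin = 2,
               seed = seed)
}
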