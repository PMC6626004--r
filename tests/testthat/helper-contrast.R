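# Synthetic factorial results with a known generating model, for
# parameter-recovery checks of the contrast regressions.
toy_design <- function(n_factors = 6) {
  sets <- default_parameter_sets()
  fields <- c("p_pair", "whelp_fail_base", "pair_persistence", "fed_fraction",
              "disease_freq", "removal_rate", "sex_ratio")[seq_len(n_factors)]
  cats <- rep(c("biological", "mixed", "policy"), length.out = n_factors)
  facs <- lapply(seq_len(n_factors), function(i) {
    f <- fields[i]
    a <- stats::setNames(list(0.4), f)
    b <- stats::setNames(list(0.6), f)
    factor_spec(paste0("f", i), cats[i], a, b)
  })
  build_factorial_design(facs, base = sets[["2013"]])
}

fake_results <- function(design, ev, n_iter = 200) {
  design$results <- data.frame(
    id = design$design$id,
    n_ext = as.integer(ev), n_quasi = as.integer(ev),
    p_ext = ev / n_iter, p_quasi = ev / n_iter,
    mean_GD = NA_real_, n_iter = n_iter, seed = 1L)
  class(design) <- c("pva_factorial", "pva_design")
  design
}

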