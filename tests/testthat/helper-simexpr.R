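# Full-scale benchmark run (1000 genes, 100 DE at Delta 1.5/2/3, 30+30
# samples, method defaults), shared across acceptance checks.
simexpr_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_study(n_genes = 1000, n_de = 100, deltas = c(1.5, 2, 3),
                            delta_counts = c(33, 32, 35), s1 = 30, s2 = 30,
                            seed = 0)
      fit <- find_degs(sim, seed = 0)
      cache <<- list(sim = sim, fit = fit, det = detection_table(sim, fit))
    }
    cache
  }
})
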