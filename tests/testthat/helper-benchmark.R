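# Memoized standard-benchmark computations shared by the acceptance-level
# tests, so the EM fit and the fold sweep run once per session.
.bench_cache <- new.env(parent = emptyenv())

benchmark_scaling <- function() {
  if (is.null(.bench_cache$scaling)) {
    sim <- build_panel(standard_benchmark_spec())
    mask <- mask_array(1000L, typed_fraction = 0.25, seed = 20240113L)
    est <- estimate_hmm_params(sim$panel, max_iter = 10L)
    res <- run_theta_scaling(sim$panel, sim$targets, mask, est)
    .bench_cache$scaling <- list(sim = sim, mask = mask, est = est, res = res)
  }
  .bench_cache$scaling
}
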