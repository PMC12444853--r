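# The matching-accuracy benchmark grid is shared by several acceptance
# checks; compute it once per test session.
.bench_cache <- new.env(parent = emptyenv())

benchmark_grid_cached <- function() {
  if (is.null(.bench_cache$bm))
    .bench_cache$bm <- benchmark_matching(rates = c(10, 25, 50, 100),
                                          failures = c(0, 0.25, 0.5, 0.8),
                                          duration = 60, n_seeds = 10,
                                          velocity = 2, seed = 20240101)
  .bench_cache$bm
}
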