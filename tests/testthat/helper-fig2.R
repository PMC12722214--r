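# The end-to-end phantom experiment is expensive; run it once and share
# the result (and its trained models) across acceptance tests.
fig2_cache <- new.env(parent = emptyenv())

fig2_result <- function() {
  if (is.null(fig2_cache$res))
    fig2_cache$res <- run_fig2_experiment(fig2_config("full", seed = 0))
  fig2_cache$res
}
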