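# Evaluate expr under a temporary seed (restoring the caller's RNG state),
# or under the current RNG stream when seed is NULL.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
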