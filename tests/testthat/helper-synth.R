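# Shared fixtures: everything is generated in code at test time.

clean_10s <- function(seed = 1L, hr = 60, morphology = ecg_morphology())
  generate_clean_ecg(10, 200, hr, morphology = morphology, seed = seed)

clean_5s <- function(seed = 1L, hr = 72)
  generate_clean_ecg(5, 200, hr, seed = seed)

default_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_corpus_pool(n_clean = 12L, seed = 42L)
    cache
  }
})

tiny_config <- function(...)
  model_config(input_len = 40L, patch_size = 4L,
               embed_channels = c(3L, 4L), embed_kernels = c(5L, 3L),
               d_model_enc = 8L, d_model_dec = 4L,
               enc_blocks = 2L, dec_blocks = 1L, heads = 2L,
               mlp_ratio = 2, dropout = 0, smooth_kernel = 3L, ...)

# nearest-neighbour matching of detected peaks to truth within a tolerance
match_peaks <- function(truth, detected, tol) {
  if (!length(truth) || !length(detected))
    return(list(recall = 0, precision = 0))
  hit_t <- vapply(truth, function(t) any(abs(detected - t) <= tol), TRUE)
  hit_d <- vapply(detected, function(d) any(abs(truth - d) <= tol), TRUE)
  list(recall = mean(hit_t), precision = mean(hit_d))
}
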