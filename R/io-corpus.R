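# Corpus and checkpoint I/O. Corpora are plain-text: one CSV per array
# (clean, noisy, noise_level), a per-sample metadata CSV, and a JSON
# sidecar holding the mixing policy, R-peak lists and the config hash.

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits; used to stamp
# artifacts with the configuration that produced them.
config_hash <- function(x) {
  if (!is.character(x)) x <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a corpus of noisy samples to a directory
#'
#' Writes `clean.csv`, `noisy.csv`, `noise_level.csv` (one row per sample,
#' no header), `meta.csv` (category, realized SNR, pure-noise flag), and
#' `corpus.json` (mixing policy, per-sample R peaks, sampling rate, config
#' hash). Writing is atomic: files land in a temporary directory first.
#'
#' @param samples List of `noisy_sample` objects.
#' @param dir Output directory (created if needed).
#' @param policy The [mixing_policy()] used for synthesis.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(samples, dir, policy = mixing_policy()) {
  stopifnot(length(samples) >= 1L)
  tmp <- tempfile("corpus_")
  dir.create(tmp, recursive = TRUE)
  mat_of <- function(get) t(vapply(samples, get,
                                   numeric(length(samples[[1L]]$noisy$samples))))
  utils::write.table(mat_of(function(s) s$clean$samples),
                     file.path(tmp, "clean.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(mat_of(function(s) s$noisy$samples),
                     file.path(tmp, "noisy.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(mat_of(function(s) s$noise_level),
                     file.path(tmp, "noise_level.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- data.frame(
    category = vapply(samples, `[[`, 0L, "category"),
    snr_db = vapply(samples, `[[`, 0, "snr_db"),
    pure_noise = vapply(samples, function(s) isTRUE(s$pure_noise), TRUE))
  utils::write.csv(meta, file.path(tmp, "meta.csv"), row.names = FALSE)
  side <- list(fs = samples[[1L]]$noisy$fs,
               policy = unclass(policy),
               r_peaks = lapply(samples, `[[`, "r_peaks"))
  side$hash <- config_hash(side[c("fs", "policy")])
  jsonlite::write_json(side, file.path(tmp, "corpus.json"),
                       auto_unbox = TRUE, digits = NA)
  if (dir.exists(dir)) unlink(dir, recursive = TRUE)
  dir.create(dirname(dir), recursive = TRUE, showWarnings = FALSE)
  ok <- file.rename(tmp, dir)
  if (!ok) { # cross-device fallback
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(tmp, full.names = TRUE), dir, overwrite = TRUE)
    unlink(tmp, recursive = TRUE)
  }
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#' @param dir Corpus directory.
#' @return List of `noisy_sample` objects with a `policy` attribute.
#' @export
read_corpus <- function(dir) {
  need <- c("clean.csv", "noisy.csv", "noise_level.csv", "meta.csv",
            "corpus.json")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("corpus incomplete, missing: ",
                         paste(miss, collapse = ", "))
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  clean <- rd("clean.csv"); noisy <- rd("noisy.csv")
  level <- rd("noise_level.csv")
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  side <- jsonlite::read_json(file.path(dir, "corpus.json"),
                              simplifyVector = TRUE)
  fs <- side$fs
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    rp <- side$r_peaks[[i]]
    structure(list(
      clean = ecg_signal(clean[i, ], fs),
      noisy = ecg_signal(noisy[i, ], fs),
      category = as.integer(meta$category[i]),
      noise_level = as.numeric(level[i, ]),
      snr_db = meta$snr_db[i],
      r_peaks = as.integer(rp %||% integer(0)),
      pure_noise = isTRUE(meta$pure_noise[i])), class = "noisy_sample")
  })
  attr(samples, "policy") <- side$policy
  attr(samples, "hash") <- side$hash
  samples
}

#' Save a model checkpoint as JSON
#'
#' Stores the model configuration, all parameter tensors (full double
#' precision), batch-norm running statistics, and optional task
#' uncertainties, plus a config hash.
#'
#' @param model An `ecg_model`.
#' @param path Output file path (`.json`).
#' @param log_sigma Optional uncertainty parameters to store alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, log_sigma = NULL) {
  pf <- flatten_params(model$params)
  obj <- list(config = unclass(model$config),
              params = lapply(pf, function(w)
                list(v = as.numeric(w), dims = dim(w) %||% length(w))),
              state = model$state,
              log_sigma = log_sigma)
  obj$hash <- config_hash(obj$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return List with `model` (an `ecg_model`) and `log_sigma`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- obj$config
  cfg <- model_config(
    input_len = cfgl$input_len, patch_size = cfgl$patch_size,
    embed_channels = cfgl$embed_channels, embed_kernels = cfgl$embed_kernels,
    d_model_enc = cfgl$d_model_enc, d_model_dec = cfgl$d_model_dec,
    enc_blocks = cfgl$enc_blocks, dec_blocks = cfgl$dec_blocks,
    enc_heads = cfgl$enc_heads, dec_heads = cfgl$dec_heads,
    enc_ffn_hidden = cfgl$enc_ffn_hidden, dec_ffn_hidden = cfgl$dec_ffn_hidden,
    n_classes = cfgl$n_classes, dropout = cfgl$dropout,
    smooth_kernel = cfgl$smooth_kernel,
    head_dim_enc = cfgl$head_dim_enc, head_dim_dec = cfgl$head_dim_dec)
  model <- build_model(cfg, seed = 1L)
  for (nm in names(obj$params)) {
    t <- obj$params[[nm]]
    w <- as.numeric(t$v)
    if (length(t$dims) > 1L) dim(w) <- t$dims
    model$params <- set_by_path(model$params, nm, w)
  }
  model$state <- list(
    bn1 = list(mean = as.numeric(obj$state$bn1$mean),
               var = as.numeric(obj$state$bn1$var)),
    bn2 = list(mean = as.numeric(obj$state$bn2$mean),
               var = as.numeric(obj$state$bn2$var)))
  list(model = model, log_sigma = obj$log_sigma, hash = obj$hash)
}
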