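# Minimal WFDB (.hea/.dat) support: enough to read NSTDB-style noise
# records (formats 16 and 212, single .dat shared by all signals) and to
# write format-16 fixtures. physical = (digital - baseline) / gain.

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty WFDB header: ", hea_path)
  top <- strsplit(lines[[1L]], "[[:space:]]+")[[1L]]
  if (length(top) < 2L) stop("malformed WFDB record line")
  n_sig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
  n_samp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  sig <- vector("list", n_sig)
  for (i in seq_len(n_sig)) {
    f <- strsplit(lines[[i + 1L]], "[[:space:]]+")[[1L]]
    fmt <- as.integer(sub("[x:+].*$", "", f[2L]))
    gain <- 200; baseline <- 0; units <- "mV"
    if (length(f) >= 3L && grepl("^[-0-9.]", f[3L])) {
      gtok <- f[3L]
      if (grepl("/", gtok)) { units <- sub("^.*/", "", gtok); gtok <- sub("/.*$", "", gtok) }
      if (grepl("\\(", gtok)) {
        baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gtok))
        gtok <- sub("\\(.*$", "", gtok)
      }
      g <- as.numeric(gtok)
      if (is.finite(g) && g != 0) gain <- g
    }
    # adc_zero (field 5) is the baseline fallback when "(baseline)" absent
    if (length(f) >= 5L && !grepl("\\(", f[3L]) &&
        grepl("^[-0-9]+$", f[5L]) && baseline == 0)
      baseline <- as.numeric(f[5L])
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else
      paste0("sig", i - 1L)
    sig[[i]] <- list(file = f[1L], format = fmt, gain = gain,
                     baseline = baseline, units = units, desc = desc)
  }
  list(n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

read_wfdb_digital <- function(dat_path, fmt, n_sig, n_samp) {
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  if (fmt == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    m <- matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], nrow = n_sig)
  } else if (fmt == 212L) {
    b <- as.integer(raw)
    n3 <- (length(b) %/% 3L) * 3L
    b1 <- b[seq(1L, n3, by = 3L)]; b2 <- b[seq(2L, n3, by = 3L)]
    b3 <- b[seq(3L, n3, by = 3L)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
    s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4L), 0x0FL), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
    m <- matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], nrow = n_sig)
  } else stop("unsupported WFDB format: ", fmt)
  if (!is.na(n_samp) && ncol(m) > n_samp) m <- m[, seq_len(n_samp), drop = FALSE]
  m
}

#' Read one channel of a WFDB record as an ECG signal
#'
#' Minimal reader for WFDB `.hea`/`.dat` pairs (formats 16 and 212), intended
#' for NSTDB-style noise records with channels such as `"bw"`, `"em"`,
#' `"ma"`. Digital values are converted to physical units via the header's
#' gain and baseline.
#'
#' @param path Record path with or without the `.hea` extension.
#' @param channel Channel name matched (case-insensitively) against the
#'   header's signal descriptions.
#' @return An [ecg_signal] at the record's native sampling rate.
#' @export
load_noise_record <- function(path, channel) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  hd <- parse_wfdb_header(hea)
  descs <- vapply(hd$signals, `[[`, "", "desc")
  i <- which(tolower(descs) == tolower(channel))
  if (!length(i))
    stop("channel '", channel, "' not found; available channels: ",
         paste(descs, collapse = ", "))
  i <- i[[1L]]
  dat <- file.path(dirname(hea), hd$signals[[i]]$file)
  if (!file.exists(dat)) stop("WFDB data file not found: ", dat)
  fmts <- unique(vapply(hd$signals, `[[`, 0L, "format"))
  if (length(fmts) != 1L) stop("mixed-format WFDB records not supported")
  dig <- read_wfdb_digital(dat, fmts, hd$n_sig, hd$n_samp)
  phys <- (dig[i, ] - hd$signals[[i]]$baseline) / hd$signals[[i]]$gain
  ecg_signal(phys, hd$fs)
}

#' Write a multi-channel WFDB record (format 16)
#'
#' Minimal writer used to build test fixtures and export noise records.
#' Physical values are digitized with the given gain (digital =
#' round(physical * gain)), clipped to the int16 range.
#'
#' @param path Record path without extension; `.hea` and `.dat` are created.
#' @param channels Named list of numeric vectors (equal lengths), one per
#'   channel; names become the channel descriptions.
#' @param fs Sampling rate in Hz.
#' @param gain ADC gain (units per mV), default 200.
#' @return The record path, invisibly.
#' @export
write_wfdb_record <- function(path, channels, fs, gain = 200) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  n <- unique(lengths(channels))
  if (length(n) != 1L) stop("all channels must have equal length")
  rec <- basename(path)
  datf <- paste0(rec, ".dat")
  dig <- vapply(channels, function(x)
    pmin(pmax(as.integer(round(x * gain)), -32768L), 32767L),
    integer(n))
  inter <- as.integer(t(dig))  # sample-major interleaving
  writeBin(inter, paste0(path, ".dat"), size = 2L, endian = "little")
  hdr <- c(
    sprintf("%s %d %g %d", rec, length(channels), fs, n),
    vapply(seq_along(channels), function(i)
      sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s", datf, gain,
              dig[1L, i], names(channels)[i]), "")
  )
  writeLines(hdr, paste0(path, ".hea"))
  invisible(path)
}

#' Read a single-column ECG CSV
#'
#' Expects a column named `ecg` (header row). An optional leading metadata
#' line of the form `# fs=200` carries the sampling rate; otherwise `fs`
#' must be supplied.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; overridden by a `# fs=` metadata line.
#' @return An [ecg_signal].
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("fs\\s*=\\s*([0-9.]+)", first))[[1L]]
    if (length(m) == 2L) fs <- as.numeric(m[[2L]])
  }
  if (is.null(fs)) stop("sampling rate not given and no '# fs=' metadata line")
  df <- utils::read.csv(path, skip = skip)
  if (!"ecg" %in% names(df)) stop("CSV must have an 'ecg' column")
  ecg_signal(df$ecg, fs)
}

#' Write an ECG signal to CSV with an `# fs=` metadata line
#' @param x An [ecg_signal].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(x, path) {
  stopifnot(inherits(x, "ecg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", x$fs), con)
  writeLines("ecg", con)
  writeLines(format(x$samples, trim = TRUE, digits = 10), con)
  invisible(path)
}
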