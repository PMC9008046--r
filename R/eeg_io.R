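#' Construct an epoched multichannel EEG recording
#'
#' The basic data container of the package: one subject's resting-state
#' EEG cut into fixed-length epochs, stored as a numeric array of
#' dimension `n_epochs x n_channels x n_samples` in microvolts.
#'
#' @param subject_id Single string identifying the subject.
#' @param data Numeric array `[n_epochs, n_channels, n_samples]`, in uV.
#' @param channel_labels Character vector of unique channel names, one
#'   per channel, typically 10-20 montage labels.
#' @param fs Sampling rate in Hz.
#' @return An object of class `epoch_set`.
#' @examples
#' x <- epoch_set("s1", array(rnorm(2 * 3 * 100), c(2, 3, 100)),
#'                c("Fz", "Cz", "Pz"), fs = 50)
#' dim(x$data)
#' @export
epoch_set <- function(subject_id, data, channel_labels, fs) {
  x <- structure(
    list(subject_id = as.character(subject_id)[1],
         channel_labels = as.character(channel_labels),
         fs = as.numeric(fs)[1],
         data = data),
    class = "epoch_set")
  validate_epoch_set(x)
}

#' Validate an epoch_set's invariants
#'
#' Checks array shape against the channel labels, label uniqueness,
#' positive sampling rate and absence of non-finite samples.
#'
#' @param x An `epoch_set`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_epoch_set <- function(x) {
  if (!inherits(x, "epoch_set")) stop("not an epoch_set")
  d <- dim(x$data)
  if (is.null(d) || length(d) != 3L)
    stop("epoch_set data must be a 3-d array [epochs x channels x samples]")
  if (d[2] != length(x$channel_labels))
    stop("n_channels (", d[2], ") != number of channel labels (",
         length(x$channel_labels), ")")
  if (anyDuplicated(x$channel_labels))
    stop("duplicate channel labels")
  if (!is.finite(x$fs) || x$fs <= 0) stop("fs must be > 0")
  if (!all(is.finite(x$data)))
    stop("non-finite values in epoch data")
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set '%s': %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  invisible(x)
}

n_epochs   <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples  <- function(x) dim(x$data)[3]

# reorder channels to a requested canonical order (error on missing)
reorder_channels <- function(x, channels) {
  idx <- match(channels, x$channel_labels)
  if (anyNA(idx))
    stop("missing channel label(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  x$data <- x$data[, idx, , drop = FALSE]
  x$channel_labels <- channels
  validate_epoch_set(x)
  x
}

## ---------------------------------------------------------------------
## EDF (European Data Format), 16-bit integer encoding.
## Minimal fixed-layout implementation: 256-byte main header + 256 bytes
## per signal, then data records of int16 samples, little-endian.

edf_field <- function(s, width) {
  s <- as.character(s)
  s <- substr(s, 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

edf_num_field <- function(x, width = 8) {
  s <- formatC(x, digits = 6, format = "g", width = 1)
  if (nchar(s) > width) s <- formatC(x, digits = 4, format = "g", width = 1)
  edf_field(s, width)
}

unit_to_uv <- function(dim_label) {
  u <- trimws(dim_label)
  if (u %in% c("uV", "µV", "")) return(1)
  if (u == "mV") return(1e3)
  if (u == "V")  return(1e6)
  message("unrecognised EDF physical dimension '", u, "'; assuming uV")
  1
}

#' Write an epoch_set to an EDF file
#'
#' Each epoch becomes one EDF data record. Samples are quantized to
#' 16-bit integers between the per-channel physical minimum and maximum,
#' so a read-back agrees with the source only up to that quantization.
#'
#' @param x An `epoch_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path) {
  validate_epoch_set(x)
  ne <- n_epochs(x); nc <- n_channels(x); ns <- n_samples(x)
  dur <- ns / x$fs

  pmin <- apply(x$data, 2, min)
  pmax <- apply(x$data, 2, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmax[flat] + 1
  # use the header's 8-character rounded values for scaling so that the
  # written samples decode consistently
  pmin_s <- vapply(pmin, edf_num_field, "")
  pmax_s <- vapply(pmax, edf_num_field, "")
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_field("0", 8),
    edf_field(x$subject_id, 80),
    edf_field("cohgraph", 80),
    edf_field("01.01.00", 8),
    edf_field("00.00.00", 8),
    edf_field(256 * (nc + 1), 8),
    edf_field("", 44),
    edf_field(ne, 8),
    edf_num_field(dur, 8),
    edf_field(nc, 4)), con, eos = NULL)
  writeChar(paste0(vapply(x$channel_labels, edf_field, "", width = 16),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(edf_field("", 80), nc), con, eos = NULL)  # transducer
  writeChar(strrep(edf_field("uV", 8), nc), con, eos = NULL)
  writeChar(paste0(pmin_s, collapse = ""), con, eos = NULL)
  writeChar(paste0(pmax_s, collapse = ""), con, eos = NULL)
  writeChar(strrep(edf_field(dmin, 8), nc), con, eos = NULL)
  writeChar(strrep(edf_field(dmax, 8), nc), con, eos = NULL)
  writeChar(strrep(edf_field("", 80), nc), con, eos = NULL)  # prefilter
  writeChar(strrep(edf_field(ns, 8), nc), con, eos = NULL)
  writeChar(strrep(edf_field("", 32), nc), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (e in seq_len(ne)) {
    for (c in seq_len(nc)) {
      dig <- round((x$data[e, c, ] - pmin[c]) * scale[c] + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an epoch_set
#'
#' The continuous signal (concatenated data records) is segmented into
#' non-overlapping epochs of `epoch_seconds`; trailing samples that do
#' not fill an epoch are dropped with a message. Physical dimensions are
#' converted to microvolts. If `channels` is given, channels are
#' selected and reordered to that canonical order and an error is raised
#' when any is absent; by default, files containing the full 19-channel
#' 10-20 montage are reordered to [montage_1020()].
#'
#' @param path EDF file path.
#' @param epoch_seconds Epoch length in seconds (default 2).
#' @param channels Optional canonical channel order.
#' @return An `epoch_set`.
#' @export
read_edf <- function(path, epoch_seconds = 2, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                      # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  if (!is.finite(nsig) || nsig < 1 || is.na(hdr_bytes) ||
      hdr_bytes != 256 * (nsig + 1))
    stop("not a valid EDF header: ", path)
  labels <- vapply(seq_len(nsig), function(i) rd(16), "")
  vapply(seq_len(nsig), function(i) rd(80), "")
  dims   <- vapply(seq_len(nsig), function(i) rd(8), "")
  pmin   <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  pmax   <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  dmin   <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  dmax   <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  vapply(seq_len(nsig), function(i) rd(80), "")
  nsamp  <- as.integer(vapply(seq_len(nsig), function(i) rd(8), ""))
  vapply(seq_len(nsig), function(i) rd(32), "")

  if (length(unique(nsamp)) != 1L)
    stop("sampling-rate mismatch across channels (samples per record: ",
         paste(unique(nsamp), collapse = ", "), ")")
  fs <- nsamp[1] / dur

  total <- sum(nsamp) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little",
                 signed = TRUE)
  if (length(raw) < total) stop("truncated EDF data section")

  # continuous signal per channel
  sig <- matrix(0, nrow = nsig, ncol = nsamp[1] * n_rec)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(nsig)) {
      v <- raw[(pos + 1):(pos + nsamp[s])]
      pos <- pos + nsamp[s]
      sig[s, ((r - 1) * nsamp[s] + 1):(r * nsamp[s])] <-
        (v - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s]) + pmin[s]
    }
  }
  for (s in seq_len(nsig)) sig[s, ] <- sig[s, ] * unit_to_uv(dims[s])

  ns_epoch <- round(epoch_seconds * fs)
  ne <- floor(ncol(sig) / ns_epoch)
  if (ne < 1) stop("recording shorter than one epoch")
  dropped <- ncol(sig) - ne * ns_epoch
  if (dropped > 0)
    message("dropping ", dropped, " trailing samples (< one epoch)")
  data <- array(0, c(ne, nsig, ns_epoch))
  for (e in seq_len(ne))
    data[e, , ] <- sig[, ((e - 1) * ns_epoch + 1):(e * ns_epoch)]

  x <- epoch_set(subject_id, data, labels, fs)
  if (is.null(channels) && all(montage_1020() %in% labels))
    channels <- montage_1020()
  if (!is.null(channels)) x <- reorder_channels(x, channels)
  x
}

## ---------------------------------------------------------------------
## Delimited epoch matrices: a plain-text alternative to EDF, lossless.

#' Write an epoch_set as a delimited text matrix
#'
#' Plain CSV with a commented header declaring subject, sampling rate
#' and channel labels, followed by one row per (epoch, channel) with
#' samples across columns. Values are written with 17 significant
#' digits, so a read-back reproduces the array bit for bit.
#'
#' @param x An `epoch_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_matrix <- function(x, path) {
  validate_epoch_set(x)
  ne <- n_epochs(x); nc <- n_channels(x)
  hdr <- c("# cohgraph epoch matrix v1",
           paste0("# subject_id=", x$subject_id),
           paste0("# fs=", sprintf("%.17g", x$fs)),
           paste0("# n_epochs=", ne),
           paste0("# n_channels=", nc),
           paste0("# channels=", paste(x$channel_labels, collapse = ",")))
  rows <- character(ne * nc)
  k <- 1L
  for (e in seq_len(ne)) for (c in seq_len(nc)) {
    rows[k] <- paste(sprintf("%.17g", x$data[e, c, ]), collapse = ",")
    k <- k + 1L
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a delimited epoch matrix into an epoch_set
#'
#' @param path File written by [write_epoch_matrix()] (or following the
#'   same layout).
#' @param channels Optional canonical channel order to select/reorder.
#' @return An `epoch_set`.
#' @export
read_epoch_matrix <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  fs <- get("fs")
  if (is.null(fs)) stop("header does not declare fs")
  fs <- as.numeric(fs)
  ch <- get("channels")
  if (is.null(ch)) stop("header does not declare channels")
  ch <- strsplit(ch, ",")[[1]]
  ne <- as.integer(get("n_epochs") %||% NA)
  nc <- length(ch)

  cells <- strsplit(body, ",")
  lens <- lengths(cells)
  if (length(unique(lens)) != 1L) stop("ragged rows in epoch matrix")
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) stop("non-numeric or non-finite cell in epoch matrix")
  ns <- lens[1]
  if (is.na(ne)) ne <- length(body) / nc
  if (ne * nc != length(body))
    stop("row count ", length(body), " is not n_epochs*n_channels")
  data <- array(0, c(ne, nc, ns))
  k <- 0L
  for (e in seq_len(ne)) for (c in seq_len(nc)) {
    k <- k + 1L
    data[e, c, ] <- vals[((k - 1) * ns + 1):(k * ns)]
  }
  x <- epoch_set(get("subject_id") %||% "unknown", data, ch, fs)
  if (!is.null(channels)) x <- reorder_channels(x, channels)
  x
}

## ---------------------------------------------------------------------
## Covariates and result tables

#' Read a subject covariate table
#'
#' Expects a CSV with at least `subject_id` and `group` columns; `sex`,
#' `mmse` and any number of cognitive-score columns are carried along.
#'
#' @param path CSV path.
#' @return A data.frame, one row per subject.
#' @export
read_covariates <- function(path) {
  cov <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(cov))
  if (length(miss)) stop("covariate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cov$subject_id)) stop("duplicate subject_id rows")
  cov
}

# CSV writer with 17-significant-digit numeric formatting so that a
# write -> read -> write cycle is byte-identical.
write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write group-comparison and graph-metric tables
#'
#' Emits `group_comparisons.csv` (one row per measure x band, the layout
#' of a per-band comparison table) and `graph_metrics.csv` (long format:
#' subject, band, measure, value) into `dir`. Numeric columns use full
#' precision so the files reread losslessly.
#'
#' @param comparisons Data.frame from [compare_groups()].
#' @param metrics Long data.frame from [cohort_metrics()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_results <- function(comparisons, metrics, dir) {
  if (is.null(comparisons) || !nrow(comparisons))
    stop("empty comparison table")
  if (is.null(metrics) || !nrow(metrics))
    stop("empty metrics table")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "group_comparisons.csv")
  p2 <- file.path(dir, "graph_metrics.csv")
  write_csv17(comparisons, p1)
  write_csv17(metrics, p2)
  invisible(c(comparisons = p1, metrics = p2))
}

## ---------------------------------------------------------------------
## Pipeline configuration

#' Default pipeline configuration
#'
#' All analysis constants in one list: the five canonical frequency
#' bands, 5000 permutations, FDR level 0.05, stratified 70/30 splits
#' repeated 10 times, dense graphs (edge threshold 0), Louvain with 10
#' restarts at resolution 1, and 20 degree-preserving null networks with
#' 10 rewiring attempts per edge for small-worldness.
#'
#' @return A named list; see the vignette for the meaning and units of
#'   every field.
#' @export
default_config <- function() {
  list(
    bands = default_bands(),
    epoch_seconds = 2,
    n_perm = 5000,
    fdr_level = 0.05,
    train_frac = 0.7,
    n_repeats = 10,
    seed = 1L,
    edge_threshold = 0,
    louvain = list(gamma = 1, restarts = 10L),
    smallworld = list(n_null = 20L, rewires_per_edge = 10L)
  )
}

validate_config <- function(cfg) {
  b <- cfg$bands
  if (is.null(b) || !nrow(b)) stop("config: bands must be non-empty")
  if (any(b$f_low >= b$f_high)) stop("config: each band needs f_low < f_high")
  if (cfg$n_perm < 1) stop("config: permutation count must be >= 1")
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stop("config: train fraction must be in (0, 1)")
  invisible(cfg)
}

#' Write / read pipeline configuration as YAML
#'
#' @param cfg Configuration list as from [default_config()].
#' @param path YAML file path.
#' @return `read_config` returns the validated configuration list.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- cfg
  out$bands <- lapply(seq_len(nrow(cfg$bands)), function(i)
    as.list(cfg$bands[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$bands <- do.call(rbind, lapply(cfg$bands, as.data.frame))
  validate_config(cfg)
  cfg
}

#' Write / read per-band coherence graphs as long-format CSV
#'
#' One row per (band, channel_i, channel_j) upper-triangle pair with
#' its coherence, full precision, losslessly rereadable into the same
#' list of graphs.
#'
#' @param graphs Named list of `coherence_graph` objects, as returned
#'   by [subject_connectivity()].
#' @param path CSV file path.
#' @return `path` invisibly; `read_adjacency` returns the list of
#'   graphs.
#' @export
write_adjacency <- function(graphs, path) {
  if (!length(graphs)) stop("empty graph list")
  rows <- lapply(graphs, function(g) {
    idx <- which(upper.tri(g$W), arr.ind = TRUE)
    data.frame(band = g$band$name,
               f_low = g$band$f_low, f_high = g$band$f_high,
               channel_i = g$channel_labels[idx[, 1]],
               channel_j = g$channel_labels[idx[, 2]],
               coherence = g$W[idx], stringsAsFactors = FALSE)
  })
  write_csv17(do.call(rbind, rows), path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$band, levels = unique(df$band))),
         function(d) {
    labels <- unique(c(d$channel_i, d$channel_j))
    n <- length(labels)
    W <- matrix(0, n, n, dimnames = list(labels, labels))
    for (r in seq_len(nrow(d))) {
      W[d$channel_i[r], d$channel_j[r]] <- d$coherence[r]
      W[d$channel_j[r], d$channel_i[r]] <- d$coherence[r]
    }
    structure(list(band = list(name = d$band[1], f_low = d$f_low[1],
                               f_high = d$f_high[1]),
                   W = unname(W), channel_labels = labels),
              class = "coherence_graph")
  })
}
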