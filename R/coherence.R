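#' Canonical EEG frequency bands
#'
#' The five bands used throughout: delta 0.1-4, theta 4-8, alpha 8-13,
#' beta 13-30 and gamma 30-50 Hz. Band membership of a frequency bin is
#' half-open, `f_low <= f < f_high`, and the DC bin is always excluded,
#' so on a 0.5 Hz grid delta effectively starts at 0.5 Hz.
#'
#' @return Data.frame with columns `name`, `f_low`, `f_high`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             f_low = c(0.1, 4, 8, 13, 30),
             f_high = c(4, 8, 13, 30, 50),
             stringsAsFactors = FALSE)
}

#' Epoch-averaged cross-spectral density
#'
#' Estimates the cross-spectral matrix S_xy(f) for all channel pairs by
#' Welch's method with one segment per epoch: each 2-s epoch is Hann
#' tapered, Fourier transformed, and the complex cross-products are
#' averaged across epochs. With the standard geometry (400 samples at
#' 200 Hz) the frequency resolution is 0.5 Hz. Averaging across K
#' epochs is what gives the coherence estimator its degrees of freedom;
#' a single epoch would make coherence identically 1, so it is refused.
#'
#' @param epochs An `epoch_set` with at least 2 epochs.
#' @param taper `"hann"` (default) or `"none"`.
#' @return A `spectral_estimate`: list with `freqs` (Hz grid, DC
#'   included at index 1), `csd` (complex array
#'   `[n_channels, n_channels, n_freqs]`, Hermitian at every frequency)
#'   and `n_epochs_used`.
#' @export
cross_spectra <- function(epochs, taper = c("hann", "none")) {
  validate_epoch_set(epochs)
  taper <- match.arg(taper)
  ne <- n_epochs(epochs); nc <- n_channels(epochs); ns <- n_samples(epochs)
  if (ne < 2)
    stop("degenerate estimator: coherence from a single epoch is ",
         "identically 1; need >= 2 epochs")
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(ns) / (ns + 1))
  } else rep(1, ns)
  nf <- floor(ns / 2) + 1L
  freqs <- (seq_len(nf) - 1) * epochs$fs / ns
  # accumulate all nc^2 cross-products per frequency:
  # acc[f, (j-1)*nc + i] = sum_e X_i(f) * Conj(X_j(f))
  acc <- matrix(0 + 0i, nf, nc * nc)
  for (e in seq_len(ne)) {
    X <- mvfft(t(epochs$data[e, , , drop = TRUE] *
                   rep(w, each = nc)))[seq_len(nf), , drop = FALSE]
    cpp_csd_acc(acc, X)
  }
  csd <- array(t(acc / ne), c(nc, nc, nf))
  # force exactly real, non-negative auto-spectra
  for (f in seq_len(nf)) {
    di <- Re(diag(csd[, , f]))
    diag(csd[, , f]) <- pmax(di, 0) + 0i
  }
  structure(list(freqs = freqs, csd = csd,
                 channel_labels = epochs$channel_labels,
                 n_epochs_used = ne),
            class = "spectral_estimate")
}

# indices of the FFT bins inside a half-open band, DC always excluded
band_bins <- function(freqs, f_low, f_high) {
  which(freqs >= f_low & freqs < f_high & freqs > 0)
}

#' Band-averaged coherence graph
#'
#' Magnitude-squared coherence COH_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))
#' averaged over the FFT bins falling inside the half-open band
#' `[f_low, f_high)`, giving one symmetric weighted adjacency matrix W
#' with entries in \[0, 1\] and a zero diagonal (self-loops are excluded
#' from all graph measures).
#'
#' @param spec A `spectral_estimate` from [cross_spectra()].
#' @param band One-row data.frame (or list) with `name`, `f_low`,
#'   `f_high`.
#' @return A `coherence_graph`: list with `band`, `W`, `channel_labels`.
#' @export
band_coherence <- function(spec, band) {
  bins <- band_bins(spec$freqs, band$f_low, band$f_high)
  if (!length(bins))
    stop("band '", band$name, "' [", band$f_low, ", ", band$f_high,
         ") contains no FFT bins at resolution ",
         signif(diff(spec$freqs[1:2]), 4), " Hz")
  nc <- dim(spec$csd)[1]
  W <- matrix(0, nc, nc)
  for (f in bins) {
    S <- spec$csd[, , f]
    p <- Re(diag(S))
    if (any(p <= 0))
      stop("degenerate power: zero auto-spectrum in band '", band$name,
           "' (channel ", which(p <= 0)[1], ")")
    W <- W + Mod(S)^2 / outer(p, p)
  }
  W <- W / length(bins)
  W <- (W + t(W)) / 2
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 0
  structure(list(band = as.list(band)[c("name", "f_low", "f_high")],
                 W = W, channel_labels = spec$channel_labels),
            class = "coherence_graph")
}

#' Per-band coherence connectivity for one subject
#'
#' Composes [cross_spectra()] and [band_coherence()]: one coherence
#' graph per frequency band, all sharing the epoch set's channel order.
#'
#' @param epochs An `epoch_set`.
#' @param bands Data.frame of band definitions (default
#'   [default_bands()]).
#' @param taper Taper passed to [cross_spectra()].
#' @return Named list of `coherence_graph` objects, one per band.
#' @examples
#' x <- epoch_set("s1", array(rnorm(4 * 3 * 200), c(4, 3, 200)),
#'                c("Fz", "Cz", "Pz"), fs = 100)
#' g <- subject_connectivity(x)
#' round(g$alpha$W, 2)
#' @export
subject_connectivity <- function(epochs, bands = default_bands(),
                                 taper = "hann") {
  fres <- epochs$fs / n_samples(epochs)
  widths <- bands$f_high - pmax(bands$f_low, fres)
  if (any(widths < fres))
    warning("epoch length gives ", signif(fres, 3),
            " Hz resolution; band(s) ",
            paste(bands$name[widths < fres], collapse = ", "),
            " are narrower than one bin")
  spec <- cross_spectra(epochs, taper = taper)
  out <- lapply(seq_len(nrow(bands)), function(i)
    band_coherence(spec, bands[i, ]))
  names(out) <- bands$name
  out
}
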