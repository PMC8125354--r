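#' @name entropy-features
#' @title Regularity (entropy) features of a time series
#'
#' @description Approximate entropy, sample entropy and fuzzy entropy quantify
#' the regularity/predictability of a time series: low values for regular
#' signals (a sine), high values for irregular ones (white noise). All three
#' compare length-\code{m} templates of the series under the Chebyshev
#' (maximum-coordinate) distance with tolerance \code{r_abs} expressed in the
#' units of the series.
#'
#' \code{approximate_entropy} follows the Pincus definition
#' \eqn{\Phi_m - \Phi_{m+1}} with self-matches included.
#' \code{sample_entropy} follows Richman--Moorman \eqn{-\log(A/B)} with
#' self-matches excluded; when no template pair matches at either length the
#' statistic is undefined and \code{NA} is returned (documented sentinel, never
#' an error). \code{fuzzy_entropy} replaces the hard threshold by the
#' exponential membership \eqn{\exp(-(d/r)^{n})} computed on baseline-removed
#' (mean-subtracted) templates.
#'
#' @param x numeric series.
#' @param m embedding dimension (template length), default 2.
#' @param r_abs absolute tolerance (same units as \code{x}); callers usually
#'   pass \code{0.2 * sd(x)}.
#' @param n_grad gradient exponent of the fuzzy membership function, default 2.
#' @return a single non-negative number (\code{sample_entropy} may return
#'   \code{NA} when undefined).
NULL

# Internal: matrix of length-m templates (rows) of x.
embed_templates <- function(x, m) {
  N <- length(x)
  n_t <- N - m + 1L
  mat <- matrix(0, nrow = n_t, ncol = m)
  for (k in seq_len(m)) mat[, k] <- x[k:(k + n_t - 1L)]
  mat
}

# Internal: n_t x n_t Chebyshev distance matrix between rows of a template
# matrix, vectorised over template pairs one coordinate at a time.
cheb_dist <- function(tpl) {
  n_t <- nrow(tpl)
  D <- matrix(0, n_t, n_t)
  for (k in seq_len(ncol(tpl)))
    D <- pmax(D, abs(outer(tpl[, k], tpl[, k], "-")))
  D
}

#' @rdname entropy-features
#' @export
approximate_entropy <- function(x, m = 2L, r_abs) {
  N <- length(x)
  if (N < m + 2L) stop("series must have at least m + 2 points")
  if (r_abs <= 0) stop("r_abs must be positive")
  phi <- function(mm) {
    tpl <- embed_templates(x, mm)
    D <- cheb_dist(tpl)
    # self-matches included: the diagonal is zero and counts
    C <- rowMeans(D <= r_abs)
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

#' @rdname entropy-features
#' @export
sample_entropy <- function(x, m = 2L, r_abs) {
  N <- length(x)
  if (N < m + 2L) stop("series must have at least m + 2 points")
  if (r_abs <= 0) stop("r_abs must be positive")
  # Richman-Moorman: N - m templates at both lengths, self-matches excluded.
  n_t <- N - m
  count_pairs <- function(mm) {
    tpl <- embed_templates(x, mm)[seq_len(n_t), , drop = FALSE]
    D <- cheb_dist(tpl)
    (sum(D <= r_abs) - n_t) / 2
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' @rdname entropy-features
#' @export
fuzzy_entropy <- function(x, m = 2L, r_abs, n_grad = 2) {
  N <- length(x)
  if (N < m + 2L) stop("series must have at least m + 2 points")
  if (r_abs <= 0) stop("r_abs must be positive")
  n_t <- N - m
  phi <- function(mm) {
    tpl <- embed_templates(x, mm)[seq_len(n_t), , drop = FALSE]
    tpl <- tpl - rowMeans(tpl)
    D <- cheb_dist(tpl)
    mu <- exp(-(D / r_abs)^n_grad)
    (sum(mu) - n_t) / (n_t * (n_t - 1))
  }
  log(phi(m)) - log(phi(m + 1L))
}

#' Mean band power via the complex Morlet wavelet transform
#'
#' Convolves each channel with complex Morlet wavelets at 1 Hz-spaced centre
#' frequencies spanning the band, and returns the mean over time and over
#' centre frequencies of the squared transform magnitude. The wavelets are
#' L2-normalised, so the output is linear in squared signal amplitude
#' (doubling the amplitude of a sinusoid quadruples its band power).
#'
#' @param epoch channels x samples numeric matrix (a single vector is treated
#'   as one channel).
#' @param fs sampling rate in Hz.
#' @param band \code{c(lo, hi)} band edges in Hz, inside \code{(0, fs/2)}.
#' @param n_cycles number of wavelet cycles (time-frequency trade-off),
#'   default 7.
#' @return numeric vector of per-channel mean band power.
#' @export
morlet_band_power <- function(epoch, fs, band, n_cycles = 7) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1L)
  n_samp <- ncol(epoch)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie inside (0, fs/2)")
  freqs <- seq(band[1], band[2], by = 1)
  pow <- matrix(0, nrow = nrow(epoch), ncol = length(freqs))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sd_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3 * sd_t * fs)
    if (2L * half + 1L > n_samp)
      stop("wavelet support exceeds epoch length; reduce n_cycles or lengthen the epoch")
    tt <- (-half:half) / fs
    w <- exp(-tt^2 / (2 * sd_t^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))        # unit-energy wavelet
    L <- n_samp + length(w) - 1L
    nfft <- stats::nextn(L, 2)
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    for (ch in seq_len(nrow(epoch))) {
      X <- stats::fft(c(epoch[ch, ], rep(0, nfft - n_samp)))
      conv <- stats::fft(X * W, inverse = TRUE) / nfft
      centre <- conv[(half + 1L):(half + n_samp)]   # "same" alignment
      pow[ch, fi] <- mean(Mod(centre)^2)
    }
  }
  rowMeans(pow)
}

#' Feature-extraction specification
#'
#' @param kind \code{"entropy"} (approximate, sample and fuzzy entropy per
#'   channel: 3 features per channel) or \code{"spectral"} (mean Morlet band
#'   power per band per channel).
#' @param m,r_frac,n_grad entropy parameters: embedding dimension, tolerance as
#'   a fraction of the series standard deviation, and fuzzy gradient exponent.
#'   Defaults \code{m = 2}, \code{r_frac = 0.2}, \code{n_grad = 2} follow the
#'   dominant convention for biosignal entropy features.
#' @param bands named list of \code{c(lo, hi)} bands in Hz (spectral kind).
#' @param n_cycles Morlet cycle count, default 7.
#' @param normalize if \code{TRUE}, min-max normalize each feature column to
#'   [0, 1] over the whole extracted table (off by default).
#' @return an object of class \code{feature_spec}.
#' @export
feature_spec <- function(kind = c("entropy", "spectral"), m = 2L, r_frac = 0.2,
                         n_grad = 2,
                         bands = list(alpha = c(12, 15), beta = c(16, 22)),
                         n_cycles = 7, normalize = FALSE) {
  kind <- match.arg(kind)
  if (m < 1L) stop("m must be >= 1")
  if (r_frac <= 0) stop("r_frac must be positive")
  structure(list(kind = kind, m = as.integer(m), r_frac = r_frac,
                 n_grad = n_grad, bands = bands, n_cycles = n_cycles,
                 normalize = normalize),
            class = "feature_spec")
}

#' Extract a feature table from raw epochs
#'
#' Entropy extraction yields 3 features per channel (approximate, sample and
#' fuzzy entropy, with tolerance \code{r_frac} times the channel's standard
#' deviation within the epoch); with 30 channels this is the familiar
#' 90-feature entropy space. Spectral extraction yields one mean Morlet band
#' power per (band, channel); 30 channels and 2 bands give the 60-feature
#' spectral space. Undefined sample-entropy values (no template matches) are
#' imputed with the maximum finite sample entropy observed in the table, so
#' the output is always finite.
#'
#' @param raw a \code{raw_epoch_dataset}.
#' @param spec a \code{feature_spec}.
#' @return a \code{participant_dataset} with one row per epoch.
#' @export
extract_feature_table <- function(raw, spec) {
  stopifnot(inherits(raw, "raw_epoch_dataset"), inherits(spec, "feature_spec"))
  n_ep <- length(raw$epochs)
  if (n_ep == 0L) stop("raw dataset contains no epochs")
  C <- raw$channels
  if (spec$kind == "entropy") {
    d <- 3L * C
    feat <- matrix(NA_real_, n_ep, d)
    for (e in seq_len(n_ep)) {
      ep <- raw$epochs[[e]]
      for (ch in seq_len(C)) {
        x <- ep[ch, ]
        r_abs <- spec$r_frac * stats::sd(x)
        if (r_abs == 0) r_abs <- .Machine$double.eps
        base <- 3L * (ch - 1L)
        feat[e, base + 1L] <- approximate_entropy(x, spec$m, r_abs)
        feat[e, base + 2L] <- sample_entropy(x, spec$m, r_abs)
        feat[e, base + 3L] <- fuzzy_entropy(x, spec$m, r_abs, spec$n_grad)
      }
    }
    colnames(feat) <- as.vector(t(outer(seq_len(C), c("apen", "sampen", "fuzzen"),
                                        function(ch, s) sprintf("ch%02d_%s", ch, s))))
    if (anyNA(feat)) {
      mx <- max(feat, na.rm = TRUE)
      feat[is.na(feat)] <- mx
    }
  } else {
    B <- length(spec$bands)
    d <- B * C
    feat <- matrix(NA_real_, n_ep, d)
    for (e in seq_len(n_ep)) {
      for (b in seq_len(B)) {
        feat[e, ((b - 1L) * C + 1L):(b * C)] <-
          morlet_band_power(raw$epochs[[e]], raw$fs, spec$bands[[b]],
                            spec$n_cycles)
      }
    }
    colnames(feat) <- as.vector(outer(seq_len(C), names(spec$bands),
                                      function(ch, bn) sprintf("%s_ch%02d", bn, ch)))
  }
  if (isTRUE(spec$normalize)) {
    rng <- apply(feat, 2L, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    feat <- sweep(sweep(feat, 2L, rng[1, ], "-"), 2L, span, "/")
  }
  participant_dataset(feat, raw$participant, raw$label, mode = raw$mode)
}
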