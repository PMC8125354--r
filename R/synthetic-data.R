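#' Configuration for the synthetic multi-participant generator
#'
#' The generator emulates the statistical structure that makes cross-participant
#' biosignal modelling hard: every participant is a distinct input distribution
#' (a stable per-participant offset in feature space, i.e. individual
#' differences), while the class-conditional structure relative to the
#' participant's own baseline is shared by everyone. Under that structure a
#' shuffled (improper) split keeps train and test distributions identical,
#' whereas holding out whole participants induces covariate shift.
#'
#' @param P number of participants (>= 1; even in condition mode).
#' @param n_per observations per participant per class (state mode) or per
#'   participant (condition mode).
#' @param d feature count.
#' @param delta class-effect magnitude, in feature units, applied along a fixed
#'   unit direction shared by all participants.
#' @param sigma_participant standard deviation of the per-participant offset
#'   vectors (isotropic Gaussian); this is the "individual differences" knob.
#' @param sigma_noise within-participant observation noise standard deviation.
#' @param mode \code{"state"} (both classes within each participant) or
#'   \code{"condition"} (label is a participant-level attribute).
#' @param seed integer RNG seed; all randomness in the generator derives from it.
#' @param u optional unit direction (length \code{d}) for the class effect;
#'   defaults to the first coordinate axis for reproducibility and closed-form
#'   checks.
#'
#' @return an object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(P, n_per, d, delta = 1,
                             sigma_participant = 1, sigma_noise = 1,
                             mode = c("state", "condition"), seed = 1L,
                             u = NULL) {
  mode <- match.arg(mode)
  P <- as.integer(P); n_per <- as.integer(n_per); d <- as.integer(d)
  if (P < 1L) stop("P must be >= 1")
  if (n_per < 1L) stop("n_per must be >= 1")
  if (d < 1L) stop("d must be >= 1")
  if (delta < 0 || sigma_participant < 0 || sigma_noise < 0)
    stop("delta and sigma parameters must be non-negative")
  if (mode == "condition" && P %% 2L != 0L)
    stop("condition mode requires an even participant count for balanced class assignment")
  if (is.null(u)) {
    u <- c(1, rep(0, d - 1L))
  } else {
    if (length(u) != d) stop("u must have length d")
    nu <- sqrt(sum(u^2))
    if (nu == 0) stop("u must be a non-zero direction")
    u <- u / nu
  }
  structure(list(P = P, n_per = n_per, d = d, delta = delta,
                 sigma_participant = sigma_participant,
                 sigma_noise = sigma_noise, mode = mode,
                 seed = as.integer(seed), u = u),
            class = "synthetic_config")
}

# Internal: deterministic per-participant sub-seed below 2^31.
participant_seed <- function(seed, p) {
  as.integer((as.numeric(seed) * 1009 + 7919 * p) %% 2147483647)
}

#' Generate a synthetic multi-participant feature dataset
#'
#' Each participant p receives an offset vector o_p drawn from an isotropic
#' zero-mean Gaussian with standard deviation \code{sigma_participant}. Each
#' observation is \code{o_p + label * delta * u + noise}, with \code{u} a fixed
#' unit direction shared by all participants and isotropic noise of standard
#' deviation \code{sigma_noise}. In state mode each participant contributes
#' \code{n_per} observations of each class; in condition mode participants are
#' split evenly into a label-0 and a label-1 group (first half / second half in
#' participant order) and the class effect is applied to the participant's
#' offset itself, so classification of a held-out participant is purely a
#' between-participant problem.
#'
#' @param config a \code{synthetic_config}.
#' @return a \code{participant_dataset}; deterministic for a fixed seed.
#' @export
generate_feature_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  P <- config$P; d <- config$d; n_per <- config$n_per
  set.seed(config$seed)
  offsets <- matrix(stats::rnorm(P * d, sd = config$sigma_participant),
                    nrow = P, ncol = d)
  if (config$mode == "condition") {
    plab <- rep(c(0L, 1L), each = P %/% 2L)
    offsets <- offsets + outer(plab * config$delta, config$u)
  }
  feat_list <- vector("list", P)
  lab_list <- vector("list", P)
  n_p <- if (config$mode == "state") 2L * n_per else n_per
  for (p in seq_len(P)) {
    set.seed(participant_seed(config$seed, p))
    noise <- matrix(stats::rnorm(n_p * d, sd = config$sigma_noise),
                    nrow = n_p, ncol = d)
    x <- sweep(noise, 2L, offsets[p, ], "+")
    if (config$mode == "state") {
      lab <- rep(c(0L, 1L), each = n_per)
      x <- x + outer(lab * config$delta, config$u)
    } else {
      lab <- rep(plab[p], n_p)
    }
    feat_list[[p]] <- x
    lab_list[[p]] <- lab
  }
  features <- do.call(rbind, feat_list)
  participant <- factor(rep(sprintf("P%02d", seq_len(P)), each = n_p),
                        levels = sprintf("P%02d", seq_len(P)))
  ds <- participant_dataset(features, participant, unlist(lab_list),
                            mode = config$mode)
  attr(ds, "offsets") <- offsets
  attr(ds, "config") <- config
  ds
}

#' Generate synthetic raw multichannel epochs
#'
#' Produces epoched multichannel signals whose band structure carries the class
#' effect: each epoch is a sum of one band-limited sinusoid per configured
#' frequency band (random frequency within the band, random phase), with the
#' per-band amplitude depending on the class and on a per-participant
#' multiplicative amplitude factor, plus white noise. This emulates the
#' structure of band-power classification problems (e.g. alpha/beta changes
#' with mental state) without any claim to physiological realism.
#'
#' @param config a \code{synthetic_config}; \code{d} is ignored (feature count
#'   is determined later by feature extraction).
#' @param fs sampling rate in Hz.
#' @param channels channel count.
#' @param epoch_seconds epoch duration in seconds; \code{epoch_seconds * fs}
#'   must be at least 32 samples.
#' @param bands named list of \code{c(lo, hi)} band edges in Hz; every band
#'   must lie strictly below the Nyquist frequency.
#' @param amplitudes 2 x B matrix of per-band sinusoid amplitudes, rows are
#'   class 0 and class 1.
#' @param noise_sd white-noise standard deviation.
#' @param participant_amp_sd standard deviation of the per-participant
#'   log-normal amplitude multiplier (0 disables it).
#'
#' @return an object of class \code{raw_epoch_dataset}: list with \code{epochs}
#'   (list of channels x samples matrices), \code{label}, \code{participant},
#'   \code{fs}, \code{channels}, \code{samples}, \code{mode}.
#' @export
generate_raw_epochs <- function(config, fs = 128, channels = 30,
                                epoch_seconds = 1,
                                bands = list(alpha = c(12, 15), beta = c(16, 22)),
                                amplitudes = rbind(c(1, 1), c(2, 1)),
                                noise_sd = 0.5, participant_amp_sd = 0.2) {
  stopifnot(inherits(config, "synthetic_config"))
  n_samp <- as.integer(round(epoch_seconds * fs))
  if (n_samp < 32L) stop("epoch_seconds * fs must be at least 32 samples")
  B <- length(bands)
  if (!is.matrix(amplitudes) || nrow(amplitudes) != 2L || ncol(amplitudes) != B)
    stop("amplitudes must be a 2 x n_bands matrix (rows: class 0, class 1)")
  for (b in bands)
    if (b[2] >= fs / 2) stop("band edge at or above the Nyquist frequency")
  P <- config$P; n_per <- config$n_per
  if (config$mode == "condition") plab <- rep(c(0L, 1L), each = P %/% 2L)
  t_grid <- (seq_len(n_samp) - 1L) / fs
  epochs <- list(); label <- integer(0); participant <- character(0)
  set.seed(config$seed)
  amp_mult <- exp(stats::rnorm(P, sd = participant_amp_sd))
  for (p in seq_len(P)) {
    set.seed(participant_seed(config$seed, p))
    labs <- if (config$mode == "state") rep(c(0L, 1L), each = n_per) else
      rep(plab[p], n_per)
    for (j in seq_along(labs)) {
      y <- labs[j]
      ep <- matrix(stats::rnorm(channels * n_samp, sd = noise_sd),
                   nrow = channels, ncol = n_samp)
      for (b in seq_len(B)) {
        lo <- bands[[b]][1]; hi <- bands[[b]][2]
        for (ch in seq_len(channels)) {
          f <- stats::runif(1, lo, hi)
          phase <- stats::runif(1, 0, 2 * pi)
          ep[ch, ] <- ep[ch, ] + amp_mult[p] * amplitudes[y + 1L, b] *
            sin(2 * pi * f * t_grid + phase)
        }
      }
      epochs[[length(epochs) + 1L]] <- ep
      label <- c(label, y)
      participant <- c(participant, sprintf("P%02d", p))
    }
  }
  structure(list(epochs = epochs, label = label,
                 participant = factor(participant,
                                      levels = sprintf("P%02d", seq_len(P))),
                 fs = fs, channels = channels, samples = n_samp,
                 bands = bands, mode = config$mode),
            class = "raw_epoch_dataset")
}

#' @export
print.raw_epoch_dataset <- function(x, ...) {
  cat("raw_epoch_dataset (", x$mode, " mode)\n", sep = "")
  cat("  epochs: ", length(x$epochs), " of ", x$channels, " channels x ",
      x$samples, " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  participants: ", nlevels(x$participant), "\n", sep = "")
  invisible(x)
}

#' Write raw epochs as per-participant CSV files plus a JSON manifest
#'
#' @param raw a \code{raw_epoch_dataset}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_raw_epochs <- function(raw, dir) {
  stopifnot(inherits(raw, "raw_epoch_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (pp in levels(raw$participant)) {
    idx <- which(raw$participant == pp)
    # one row per (epoch, channel)
    mat <- do.call(rbind, raw$epochs[idx])
    df <- data.frame(epoch = rep(idx, each = raw$channels),
                     channel = rep(seq_len(raw$channels), length(idx)),
                     mat, check.names = FALSE)
    f <- file.path(dir, paste0(pp, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(fs = raw$fs, channels = raw$channels,
                   samples = raw$samples, mode = raw$mode,
                   participants = levels(raw$participant),
                   files = files, labels = raw$label,
                   epoch_participant = as.character(raw$participant))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
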