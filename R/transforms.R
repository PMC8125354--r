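#' Inter-participant variability-reducing transformations
#'
#' Both transformations are computed on, and applied to, the full dataset
#' before any partitioning, which is how their effect on improper vs. proper
#' accuracy is studied. They are oracle transformations: shift-to-median uses
#' the class labels of every participant, including any participant that will
#' later be held out, and the per-participant Heaviside medians are computed
#' from each participant's own data. Using them in a deployed pipeline would
#' itself be a form of leakage, so both functions require
#' \code{leakage_acknowledged = TRUE}; they exist to demonstrate the
#' relationship between inter-participant variability and covariate shift, not
#' as a practical preprocessing recommendation.
#'
#' @name variability-transforms
NULL

#' @describeIn variability-transforms Per-participant, per-feature binarisation
#'   at the participant's feature median: the output is 1 where the value is
#'   strictly greater than the median, 0 where it is less than or equal
#'   (ties map to 0). Medians use the usual order-statistic rule (middle
#'   element for odd counts, mean of the two middle elements for even counts).
#'
#' @param ds a \code{participant_dataset}.
#' @param leakage_acknowledged must be set to \code{TRUE}; see Details.
#' @param train_participants optional character vector of participant levels to
#'   compute medians from. Participants outside this set are binarised at the
#'   pooled median of the training participants' data (the non-oracle variant).
#'   Default \code{NULL} uses each participant's own data.
#' @return a \code{participant_dataset} with binary features; the
#'   \code{"transform_record"} attribute holds the per-participant median
#'   vectors.
#' @export
shifted_heaviside <- function(ds, leakage_acknowledged = FALSE,
                              train_participants = NULL) {
  stopifnot(inherits(ds, "participant_dataset"))
  if (!isTRUE(leakage_acknowledged))
    stop("this is an oracle transformation computed across the full dataset; ",
         "set leakage_acknowledged = TRUE to apply it")
  by_p <- participant_indices(ds)
  feat <- ds$features
  out <- matrix(0, nrow(feat), ncol(feat), dimnames = dimnames(feat))
  medians <- matrix(NA_real_, length(by_p), ncol(feat),
                    dimnames = list(names(by_p), colnames(feat)))
  global_med <- NULL
  if (!is.null(train_participants)) {
    tr_idx <- which(ds$participant %in% train_participants)
    if (!length(tr_idx)) stop("train_participants matches no data")
    global_med <- apply(feat[tr_idx, , drop = FALSE], 2L, stats::median)
  }
  for (pp in names(by_p)) {
    idx <- by_p[[pp]]
    med <- if (is.null(train_participants) || pp %in% train_participants)
      apply(feat[idx, , drop = FALSE], 2L, stats::median)
    else global_med
    medians[pp, ] <- med
    out[idx, ] <- (sweep(feat[idx, , drop = FALSE], 2L, med, "-") > 0) + 0
  }
  res <- participant_dataset(out, ds$participant, ds$label, mode = ds$mode)
  attr(res, "transform_record") <- list(kind = "shifted_heaviside",
                                        participant_medians = medians)
  res
}

#' @describeIn variability-transforms Per-(participant, class) translation that
#'   re-centres each participant's class median onto the pooled class median:
#'   for every feature, the pooled class median \eqn{\tilde C_y} is computed
#'   over all observations of class y across participants, the participant
#'   centroid \eqn{\tilde c_{p,y}} over participant p's class-y observations,
#'   and every observation is shifted by \eqn{\tilde C_y - \tilde c_{p,y}}.
#'   Being a per-block translation it preserves all pairwise distances within
#'   each (participant, class) block, and applying it twice is the identity on
#'   the already-shifted data.
#' @export
shift_to_median <- function(ds, leakage_acknowledged = FALSE) {
  stopifnot(inherits(ds, "participant_dataset"))
  if (!isTRUE(leakage_acknowledged))
    stop("this transformation consumes the labels of all participants, ",
         "including held-out ones; set leakage_acknowledged = TRUE to apply it")
  feat <- ds$features
  out <- feat
  classes <- sort(unique(ds$label))
  pooled <- list()
  centroids <- list()
  for (y in classes) {
    cy_idx <- which(ds$label == y)
    C_y <- apply(feat[cy_idx, , drop = FALSE], 2L, stats::median)
    pooled[[as.character(y)]] <- C_y
    for (pp in levels(ds$participant)) {
      idx <- which(ds$participant == pp & ds$label == y)
      if (!length(idx)) next
      c_py <- apply(feat[idx, , drop = FALSE], 2L, stats::median)
      centroids[[paste(pp, y, sep = ".")]] <- c_py
      out[idx, ] <- sweep(feat[idx, , drop = FALSE], 2L, C_y - c_py, "+")
    }
  }
  res <- participant_dataset(out, ds$participant, ds$label, mode = ds$mode)
  attr(res, "transform_record") <- list(kind = "shift_to_median",
                                        pooled_class_medians = pooled,
                                        participant_class_centroids = centroids)
  res
}

#' Retrieve the transformation record of a transformed dataset
#'
#' @param ds a dataset returned by \code{\link{shifted_heaviside}} or
#'   \code{\link{shift_to_median}}.
#' @return the record list (kind plus median/centroid vectors), or \code{NULL}.
#' @export
transform_record <- function(ds) attr(ds, "transform_record")
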