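#' Multi-participant feature dataset
#'
#' Container for a feature table in which every observation belongs to exactly
#' one participant and carries a binary class label. This is the object every
#' stage of the pipeline consumes: partition constructors, transformations,
#' diagnostics and the cross-validation harness.
#'
#' Two labelling modes are distinguished. In \code{"state"} mode the class is a
#' within-participant state (e.g. fatigued vs. alert), so both labels occur
#' within every participant. In \code{"condition"} mode the class is a
#' participant-level attribute (e.g. diagnosed vs. control), so all of a
#' participant's observations share one label.
#'
#' @param features numeric matrix, observations in rows, features in columns.
#' @param participant vector of participant identifiers, one per row of
#'   \code{features}; coerced to factor.
#' @param label integer/numeric vector of 0/1 class labels, one per row.
#' @param mode \code{"state"} or \code{"condition"}.
#'
#' @return An object of class \code{participant_dataset}: a list with elements
#'   \code{features}, \code{participant} (factor), \code{label} (integer),
#'   \code{mode} and \code{n}.
#' @export
participant_dataset <- function(features, participant, label,
                                mode = c("state", "condition")) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  participant <- as.factor(participant)
  label <- as.integer(label)
  if (length(participant) != n || length(label) != n)
    stop("participant and label must have one entry per row of features")
  if (anyNA(features) || anyNA(participant) || anyNA(label))
    stop("participant_dataset must not contain missing values")
  if (!all(label %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  if (n == 0L)
    stop("participant_dataset must contain at least one observation")
  per <- split(label, participant, drop = TRUE)
  if (mode == "condition") {
    bad <- names(per)[vapply(per, function(l) length(unique(l)) != 1L, logical(1))]
    if (length(bad))
      stop("condition mode requires a constant label within each participant; violated by: ",
           paste(bad, collapse = ", "))
  } else {
    bad <- names(per)[vapply(per, function(l) length(unique(l)) != 2L, logical(1))]
    if (length(bad))
      stop("state mode requires both labels within every participant; violated by: ",
           paste(bad, collapse = ", "))
  }
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%04d", seq_len(ncol(features)))
  structure(list(features = features,
                 participant = droplevels(participant),
                 label = label,
                 mode = mode,
                 n = n),
            class = "participant_dataset")
}

#' @export
print.participant_dataset <- function(x, ...) {
  cat("participant_dataset (", x$mode, " mode)\n", sep = "")
  cat("  observations: ", x$n, "\n", sep = "")
  cat("  features:     ", ncol(x$features), "\n", sep = "")
  cat("  participants: ", nlevels(x$participant), "\n", sep = "")
  cat("  label counts: 0: ", sum(x$label == 0L), ", 1: ", sum(x$label == 1L),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.participant_dataset <- function(object, ...) {
  tab <- table(participant = object$participant, label = object$label)
  cat("participant_dataset summary (", object$mode, " mode)\n", sep = "")
  print(tab)
  invisible(tab)
}

#' Number of participants in a dataset
#' @param ds a \code{participant_dataset}.
#' @return integer participant count.
#' @export
n_participants <- function(ds) {
  stopifnot(inherits(ds, "participant_dataset"))
  nlevels(ds$participant)
}

#' Write a participant dataset as delimited text
#'
#' The layout is one row per observation with columns
#' \code{participant_id,label,f0001..fNNNN}.
#'
#' @param ds a \code{participant_dataset}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "participant_dataset"))
  df <- data.frame(participant_id = as.character(ds$participant),
                   label = ds$label,
                   ds$features,
                   check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a participant dataset written by \code{write_dataset_csv}
#'
#' @param path CSV path with columns \code{participant_id}, \code{label} and
#'   feature columns.
#' @param mode labelling mode of the stored data.
#' @return a \code{participant_dataset}.
#' @export
read_dataset_csv <- function(path, mode = c("state", "condition")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "label") %in% names(df)))
    stop("expected columns participant_id and label")
  feat <- as.matrix(df[, setdiff(names(df), c("participant_id", "label")), drop = FALSE])
  participant_dataset(feat, df$participant_id, df$label, mode = mode)
}

# Internal: row indices per participant, in level order.
participant_indices <- function(ds) {
  split(seq_len(ds$n), ds$participant)
}
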