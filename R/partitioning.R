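#' Cross-validation partition plans
#'
#' A partition plan is an ordered list of folds, each holding a train index set
#' and an evaluation index set, plus the policy that produced it. Three
#' policies are provided:
#' \itemize{
#'   \item \code{improper_kfold}: all observations shuffled together and split
#'     into k near-equal evaluation folds, ignoring participant identity. Every
#'     participant typically contributes to both train and evaluation of every
#'     fold, which inflates cross-participant accuracy estimates.
#'   \item \code{proper_lopo}: Leave-One-Participant-Out; one fold per
#'     participant.
#'   \item \code{proper_lnpo}: Leave-N-Participants-Out; participants are
#'     shuffled and divided into groups whose observations form the evaluation
#'     folds.
#' }
#' All constructors produce exact cross-validation plans: evaluation sets are
#' pairwise disjoint and their union covers every observation exactly once.
#'
#' @name partition-plans
NULL

new_partition_plan <- function(folds, policy, k, seed = NA_integer_) {
  structure(list(folds = folds, policy = policy, k = as.integer(k),
                 seed = seed),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat("partition_plan: ", x$policy, ", ", x$k, " folds\n", sep = "")
  ne <- vapply(x$folds, function(f) length(f$eval), integer(1))
  nt <- vapply(x$folds, function(f) length(f$train), integer(1))
  cat("  eval sizes:  ", paste(ne, collapse = " "), "\n", sep = "")
  cat("  train sizes: ", paste(nt, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @describeIn partition-plans improper shuffled k-fold plan (participants
#'   mixed across train and evaluation).
#' @param ds a \code{participant_dataset}.
#' @param k number of folds (>= 2, <= n).
#' @param seed RNG seed for the shuffle.
#' @param stratify if \code{TRUE}, shuffle within class labels so folds are
#'   approximately class-balanced; off by default.
#' @return a \code{partition_plan}.
#' @export
improper_shuffled_kfold <- function(ds, k, seed = 1L, stratify = FALSE) {
  stopifnot(inherits(ds, "participant_dataset"))
  n <- ds$n
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of observations")
  set.seed(seed)
  if (stratify) {
    idx0 <- sample(which(ds$label == 0L))
    idx1 <- sample(which(ds$label == 1L))
    fold_of <- integer(n)
    fold_of[idx0] <- rep_len(seq_len(k), length(idx0))
    fold_of[idx1] <- rep_len(seq_len(k), length(idx1))
  } else {
    perm <- sample.int(n)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold_of <- integer(n)
    fold_of[perm] <- rep(seq_len(k), times = sizes)
  }
  folds <- lapply(seq_len(k), function(f) {
    ev <- which(fold_of == f)
    list(train = setdiff(seq_len(n), ev), eval = ev)
  })
  new_partition_plan(folds, "improper_kfold", k, as.integer(seed))
}

#' @describeIn partition-plans Leave-One-Participant-Out plan; folds follow
#'   participant first-appearance (level) order.
#' @export
lopo_partition <- function(ds) {
  stopifnot(inherits(ds, "participant_dataset"))
  P <- n_participants(ds)
  if (P < 2L) stop("LOPO requires at least 2 participants")
  by_p <- participant_indices(ds)
  folds <- lapply(levels(ds$participant), function(pp) {
    ev <- by_p[[pp]]
    list(train = setdiff(seq_len(ds$n), ev), eval = ev)
  })
  new_partition_plan(folds, "proper_lopo", P)
}

#' @describeIn partition-plans Leave-N-Participants-Out plan: participants are
#'   shuffled and dealt round-robin into \code{n_folds} groups of size
#'   floor(P/n_folds) or ceiling(P/n_folds).
#' @param n_folds number of participant groups (2 <= n_folds <= P).
#' @export
lnpo_partition <- function(ds, n_folds, seed = 1L) {
  stopifnot(inherits(ds, "participant_dataset"))
  P <- n_participants(ds)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_folds > P) stop("n_folds must not exceed the participant count")
  set.seed(seed)
  order_p <- sample(levels(ds$participant))
  group_of <- rep_len(seq_len(n_folds), P)      # round-robin over the shuffle
  by_p <- participant_indices(ds)
  folds <- lapply(seq_len(n_folds), function(g) {
    pps <- order_p[group_of == g]
    ev <- sort(unlist(by_p[pps], use.names = FALSE))
    list(train = setdiff(seq_len(ds$n), ev), eval = ev)
  })
  new_partition_plan(folds, "proper_lnpo", n_folds, as.integer(seed))
}

#' Audit a partition plan for participant leakage
#'
#' A fold violates the proper-partitioning rule whenever any participant
#' appears in both its train and its evaluation set. The audit counts the
#' violating (fold, participant) pairs, infers the policy actually realised
#' (proper iff zero violations), and compares it against the declared policy.
#'
#' @param plan a \code{partition_plan}.
#' @param ds the \code{participant_dataset} the plan indexes into.
#' @return an object of class \code{partition_audit}: list with
#'   \code{violations} (data.frame of fold/participant pairs),
#'   \code{violations_per_fold}, \code{inferred_policy} (\code{"proper"} or
#'   \code{"improper"}), \code{declared_policy} and \code{pass} (TRUE iff the
#'   inferred policy is consistent with the declared one).
#' @export
audit_partition <- function(plan, ds) {
  stopifnot(inherits(plan, "partition_plan"), inherits(ds, "participant_dataset"))
  all_idx <- unlist(lapply(plan$folds, function(f) c(f$train, f$eval)))
  if (any(all_idx < 1L | all_idx > ds$n))
    stop("plan contains indices outside the dataset")
  vio <- list()
  per_fold <- integer(length(plan$folds))
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    shared <- intersect(unique(ds$participant[fold$train]),
                        unique(ds$participant[fold$eval]))
    per_fold[f] <- length(shared)
    if (length(shared))
      vio[[length(vio) + 1L]] <- data.frame(fold = f,
                                            participant = as.character(shared),
                                            stringsAsFactors = FALSE)
  }
  violations <- if (length(vio)) do.call(rbind, vio) else
    data.frame(fold = integer(0), participant = character(0),
               stringsAsFactors = FALSE)
  inferred <- if (nrow(violations) == 0L) "proper" else "improper"
  declared_proper <- plan$policy %in% c("proper_lopo", "proper_lnpo")
  pass <- (inferred == "proper") == declared_proper
  structure(list(violations = violations,
                 violations_per_fold = per_fold,
                 n_violations = nrow(violations),
                 inferred_policy = inferred,
                 declared_policy = plan$policy,
                 pass = pass),
            class = "partition_audit")
}

#' @export
print.partition_audit <- function(x, ...) {
  cat("partition audit: declared ", x$declared_policy, ", inferred ",
      x$inferred_policy, "\n", sep = "")
  cat("  violating (fold, participant) pairs: ", x$n_violations, "\n", sep = "")
  cat(if (x$pass) "  PASS: plan is consistent with its declared policy\n"
      else "  FAIL: plan is inconsistent with its declared policy\n")
  invisible(x)
}

#' Serialize or restore a partition plan as JSON
#'
#' Plans are stored as \code{{policy, k, seed, folds: [{train, eval}, ...]}}
#' with 0-based indices for interoperability.
#'
#' @param plan a \code{partition_plan}.
#' @param path JSON file path.
#' @return \code{write_partition_json}: \code{path}, invisibly;
#'   \code{read_partition_json}: a \code{partition_plan}.
#' @export
write_partition_json <- function(plan, path) {
  stopifnot(inherits(plan, "partition_plan"))
  obj <- list(policy = plan$policy, k = plan$k, seed = plan$seed,
              folds = lapply(plan$folds, function(f)
                list(train = f$train - 1L, eval = f$eval - 1L)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(nrow_or_len(obj$folds)), function(i) {
    f <- if (is.data.frame(obj$folds)) obj$folds[i, ] else obj$folds[[i]]
    list(train = as.integer(unlist(f$train)) + 1L,
         eval = as.integer(unlist(f$eval)) + 1L)
  })
  new_partition_plan(folds, obj$policy, obj$k,
                     if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed))
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
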