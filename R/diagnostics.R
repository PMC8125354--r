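#' Histogram KL divergence between two samples
#'
#' Estimates D(P_a || P_b) = sum p_a log(p_a / p_b) (natural log) from two
#' samples using a shared equal-width binning over the pooled range of each
#' coordinate. Both histograms are epsilon-smoothed (a small mass added to
#' every cell) and renormalised, so the divergence is always finite; it is 0
#' exactly when the smoothed histograms coincide, in particular whenever the
#' two samples are identical.
#'
#' @param sample_a,sample_b numeric matrices (observations x dimensions) or
#'   vectors; must share the same dimensionality.
#' @param bins bins per dimension, default 10.
#' @param epsilon smoothing mass added to each cell before renormalisation.
#' @return a non-negative number (nats).
#' @export
histogram_kl <- function(sample_a, sample_b, bins = 10L, epsilon = 1e-5) {
  if (is.vector(sample_a)) sample_a <- matrix(sample_a, ncol = 1L)
  if (is.vector(sample_b)) sample_b <- matrix(sample_b, ncol = 1L)
  if (nrow(sample_a) == 0L || nrow(sample_b) == 0L)
    stop("both samples must be non-empty")
  if (ncol(sample_a) != ncol(sample_b))
    stop("samples must share dimensionality")
  d <- ncol(sample_a)
  cell_a <- rep(0L, nrow(sample_a))
  cell_b <- rep(0L, nrow(sample_b))
  for (j in seq_len(d)) {
    rng <- range(c(sample_a[, j], sample_b[, j]))
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)   # degenerate axis
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    ia <- findInterval(sample_a[, j], edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    ib <- findInterval(sample_b[, j], edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    cell_a <- cell_a * bins + (ia - 1L)
    cell_b <- cell_b * bins + (ib - 1L)
  }
  lev <- sort(unique(c(cell_a, cell_b)))
  pa <- tabulate(match(cell_a, lev), nbins = length(lev)) / nrow(sample_a)
  pb <- tabulate(match(cell_b, lev), nbins = length(lev)) / nrow(sample_b)
  kl_divergence(pa, pb, epsilon = epsilon)
}

#' KL divergence between two discrete distributions
#'
#' @param p,q non-negative weight vectors of equal length (renormalised
#'   internally).
#' @param epsilon optional smoothing mass added to every cell of both
#'   distributions before renormalisation; with \code{epsilon = 0}, cells where
#'   \code{p > 0} but \code{q = 0} give \code{Inf}.
#' @return D(p || q) in nats.
#' @export
kl_divergence <- function(p, q, epsilon = 0) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  p <- p + epsilon; q <- q + epsilon
  p <- p / sum(p); q <- q / sum(q)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Two-component PCA projection
#'
#' Mean-centred projection onto the top two principal components, fitted on the
#' pooled observations of the partitioning method under study (train and test
#' of one split together, so both live in one common plane).
#'
#' @param x numeric matrix, n x d with n >= 3 and d >= 2.
#' @return list with \code{scores} (n x 2), \code{var_explained} (two
#'   non-increasing fractions in [0, 1]) and \code{rotation} (d x 2 orthonormal
#'   loadings).
#' @export
pca2_project <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L || ncol(x) < 2L) stop("need n >= 3 and d >= 2")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) == 0) stop("input has rank 0 (all rows identical)")
  k <- ncol(pc$x)
  scores <- matrix(0, nrow(x), 2L)
  rotation <- matrix(0, ncol(x), 2L)
  var_explained <- c(0, 0)
  take <- min(2L, k)
  scores[, seq_len(take)] <- pc$x[, seq_len(take)]
  rotation[, seq_len(take)] <- pc$rotation[, seq_len(take)]
  var_explained[seq_len(take)] <- (ev / sum(ev))[seq_len(take)]
  list(scores = scores, var_explained = var_explained, rotation = rotation)
}

#' Density-ratio weight grid over a 2-D projection
#'
#' Estimates the training and test input densities with a shared 2-D histogram
#' (default 7 x 7 = 49 bins spanning the pooled min-max of each axis) and forms
#' the per-bin importance weights w = test density / train density: the
#' instance weights that would rescale a training loss to approximate the test
#' loss under covariate shift. For display, log10(w + epsilon) is attached, so
#' bins with train mass but no test mass sit at exactly log10(epsilon) (-5 at
#' the default epsilon). Bins with test mass but no train mass have no defined
#' weight (the zero-denominator case: loss rescaling requires the training
#' distribution to cover the test support) and are flagged in
#' \code{unsupported}.
#'
#' @param train2d,test2d n x 2 numeric matrices of projected coordinates.
#' @param n_bins bins per axis, default 7.
#' @param epsilon stabiliser added inside the log, default 1e-5.
#' @return an object of class \code{weight_grid}: list with \code{x_edges},
#'   \code{y_edges}, \code{train_density}, \code{test_density}, \code{ratio},
#'   \code{log_ratio}, \code{unsupported} (logical mask), \code{epsilon},
#'   \code{n_bins}. Matrices are n_bins x n_bins with x binned on rows.
#' @export
weight_ratio_grid <- function(train2d, test2d, n_bins = 7L, epsilon = 1e-5) {
  train2d <- as.matrix(train2d); test2d <- as.matrix(test2d)
  if (nrow(train2d) == 0L || nrow(test2d) == 0L)
    stop("both samples must be non-empty")
  if (ncol(train2d) != 2L || ncol(test2d) != 2L)
    stop("inputs must be n x 2 coordinate matrices")
  pooled <- rbind(train2d, test2d)
  xr <- range(pooled[, 1]); yr <- range(pooled[, 2])
  if (xr[1] == xr[2] || yr[1] == yr[2])
    stop("degenerate (zero-width) axis range")
  x_edges <- seq(xr[1], xr[2], length.out = n_bins + 1L)
  y_edges <- seq(yr[1], yr[2], length.out = n_bins + 1L)
  bin2d <- function(pts) {
    ix <- findInterval(pts[, 1], x_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    iy <- findInterval(pts[, 2], y_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    cnt <- matrix(0, n_bins, n_bins)
    for (i in seq_len(nrow(pts))) cnt[ix[i], iy[i]] <- cnt[ix[i], iy[i]] + 1
    cnt / nrow(pts)
  }
  ptr <- bin2d(train2d)
  pte <- bin2d(test2d)
  ratio <- matrix(NA_real_, n_bins, n_bins)
  supp <- ptr > 0
  ratio[supp] <- pte[supp] / ptr[supp]
  unsupported <- !supp & pte > 0
  log_ratio <- matrix(NA_real_, n_bins, n_bins)
  log_ratio[supp] <- log10(ratio[supp] + epsilon)
  structure(list(x_edges = x_edges, y_edges = y_edges,
                 train_density = ptr, test_density = pte,
                 ratio = ratio, log_ratio = log_ratio,
                 unsupported = unsupported,
                 epsilon = epsilon, n_bins = as.integer(n_bins)),
            class = "weight_grid")
}

#' @export
print.weight_grid <- function(x, ...) {
  occ <- sum(x$train_density > 0 | x$test_density > 0)
  cat("weight_grid: ", x$n_bins, " x ", x$n_bins, " bins (", occ,
      " occupied), epsilon = ", format(x$epsilon), "\n", sep = "")
  supp <- !is.na(x$ratio)
  cat("  supported bins: ", sum(supp), "; unsupported (test mass, no train mass): ",
      sum(x$unsupported), "\n", sep = "")
  cat("  mean |log10 w| over occupied supported bins: ",
      round(mean(abs(x$log_ratio[supp & (x$train_density > 0)]), na.rm = TRUE), 3),
      "\n", sep = "")
  invisible(x)
}

#' Heat-map display of a weight grid
#'
#' @param x a \code{weight_grid}.
#' @param main plot title.
#' @param ... passed to \code{graphics::image}.
#' @return invisibly, \code{x}.
#' @export
plot.weight_grid <- function(x, main = "log10 density-ratio weights", ...) {
  z <- x$log_ratio
  graphics::image(x = (x$x_edges[-1] + x$x_edges[-length(x$x_edges)]) / 2,
                  y = (x$y_edges[-1] + x$y_edges[-length(x$y_edges)]) / 2,
                  z = z, xlab = "PC1", ylab = "PC2", main = main, ...)
  invisible(x)
}

#' Serialize a weight grid as JSON
#'
#' @param grid a \code{weight_grid}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_weight_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "weight_grid"))
  obj <- list(x_edges = grid$x_edges, y_edges = grid$y_edges,
              train_density = grid$train_density,
              test_density = grid$test_density,
              ratio = grid$ratio, log_ratio = grid$log_ratio,
              unsupported = grid$unsupported, epsilon = grid$epsilon,
              n_bins = grid$n_bins)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor", na = "null")
  invisible(path)
}

#' Per-bin difference of two log-ratio heat maps
#'
#' Computes log10(w_a + eps) - log10(w_b + eps) per bin (typically a proper
#' minus an improper grid on the same geometry) and labels each bin
#' \code{"="} when the absolute delta is within \code{tau},
#' \code{"v"} for a significant negative delta and \code{"+"} for a
#' significant positive delta. Bins undefined in either grid give \code{NA}.
#'
#' @param grid_a,grid_b two \code{weight_grid}s with identical edges and
#'   epsilon.
#' @param tau label threshold in log10 units, default 0.5.
#' @return list with \code{delta} (matrix), \code{labels} (character matrix)
#'   and per-label counts \code{n_equal}, \code{n_neg}, \code{n_pos}.
#' @export
log_ratio_delta <- function(grid_a, grid_b, tau = 0.5) {
  stopifnot(inherits(grid_a, "weight_grid"), inherits(grid_b, "weight_grid"))
  if (!isTRUE(all.equal(grid_a$x_edges, grid_b$x_edges)) ||
      !isTRUE(all.equal(grid_a$y_edges, grid_b$y_edges)) ||
      grid_a$epsilon != grid_b$epsilon)
    stop("grids must share geometry and epsilon")
  delta <- grid_a$log_ratio - grid_b$log_ratio
  labels <- matrix(NA_character_, nrow(delta), ncol(delta))
  labels[!is.na(delta) & abs(delta) <= tau] <- "="
  labels[!is.na(delta) & delta < -tau] <- "v"
  labels[!is.na(delta) & delta > tau] <- "+"
  list(delta = delta, labels = labels,
       n_equal = sum(labels == "=", na.rm = TRUE),
       n_neg = sum(labels == "v", na.rm = TRUE),
       n_pos = sum(labels == "+", na.rm = TRUE),
       tau = tau)
}

#' Neighbour-based participant purity
#'
#' Operationalises the visual cluster inspection of a 2-D embedding: the
#' fraction of observations whose k nearest neighbours (Euclidean distance,
#' self excluded) have a strict majority participant equal to the
#' observation's own participant. Ties are broken toward "not own", so a
#' neighbourhood split evenly between the own participant and another does not
#' count as pure. Values near 1 indicate strong clustering by participant;
#' values near the k-NN chance level indicate none.
#'
#' @param points n x 2 embedding coordinates or n x d raw features.
#' @param participant participant identifier per row.
#' @param k neighbourhood size, default 10 (must be < n).
#' @return a number in [0, 1].
#' @export
participant_purity <- function(points, participant, k = 10L) {
  points <- as.matrix(points)
  n <- nrow(points)
  participant <- as.factor(participant)
  if (nlevels(participant) < 2L) stop("need at least 2 participants")
  if (k >= n) stop("k must be smaller than the number of observations")
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  own <- 0L
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    tab <- table(participant[nb])
    mx <- max(tab)
    winners <- names(tab)[tab == mx]
    if (length(winners) == 1L && winners == as.character(participant[i]))
      own <- own + 1L
  }
  own / n
}

#' t-SNE embedding into two dimensions
#'
#' Exact (quadratic-cost) t-distributed stochastic neighbour embedding:
#' per-point Gaussian bandwidths are calibrated by bisection to the target
#' perplexity, the symmetrised neighbour distribution is matched to a
#' Student-t low-dimensional kernel by gradient descent with momentum and
#' early exaggeration, from a seeded random start. Deterministic for a fixed
#' seed. Suitable for the dataset sizes used here (hundreds to a few thousand
#' observations).
#'
#' @param features n x d numeric matrix.
#' @param perplexity target perplexity (effective neighbourhood size),
#'   default 30; requires n > 3 * perplexity.
#' @param seed RNG seed for the initial layout.
#' @param n_iter gradient-descent iterations, default 500.
#' @param learning_rate gradient step size, default 100.
#' @return an object of class \code{embedding_result}: list with
#'   \code{coords} (n x 2, finite), \code{method}, \code{perplexity},
#'   \code{seed}, \code{n_iter}.
#' @export
embed_2d <- function(features, perplexity = 30, seed = 1L, n_iter = 500L,
                     learning_rate = 100) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stop("perplexity too large: need n > 3 * perplexity")
  D2 <- as.matrix(stats::dist(X))^2
  target_H <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { hi <- beta; beta <- (lo + hi) / 2; next }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - target_H) < 1e-6) break
      if (H > target_H) { lo <- beta; beta <- if (hi == 1e20) beta * 2 else (lo + hi) / 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  exaggeration <- 12
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exaggeration else P
    dY2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + dY2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (rowSums(W) * Y - W %*% Y)
    momentum <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  structure(list(coords = Y, method = "tsne_exact",
                 perplexity = perplexity, seed = as.integer(seed),
                 n_iter = as.integer(n_iter)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("embedding_result: ", x$method, ", n = ", nrow(x$coords),
      ", perplexity = ", x$perplexity, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
plot.embedding_result <- function(x, participant = NULL, ...) {
  col <- if (is.null(participant)) "black" else as.integer(as.factor(participant))
  graphics::plot(x$coords, col = col, pch = 16, xlab = "dim 1", ylab = "dim 2",
                 main = "2-D embedding", ...)
  invisible(x)
}
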