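#' Random-forest regressor with retained out-of-bag predictions
#'
#' Thin seeded wrapper around \code{\link[randomForest]{randomForest}} with
#' conventional regression defaults (500 trees, features-per-split = p/3
#' rounded up, minimum node size 5).  Out-of-bag predictions are retained so
#' the bias correction of \code{\link{fit_bcrf}} can be fitted on them.
#'
#' @param X numeric matrix, observations x features (>= 10 rows).
#' @param y numeric response.
#' @param ntree,mtry,nodesize forest hyperparameters.
#' @param seed integer; the forest is grown under this seed, so repeated fits
#'   on identical data give identical predictions.
#' @return an object of class \code{"sensmap_rf"} with a \code{predict}
#'   method.
#' @export
fit_rf <- function(X, y, ntree = 500L, mtry = NULL, nodesize = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) alignment_error("X rows and y length differ")
  if (nrow(X) < 10L) insufficient_data_error("need at least 10 training rows")
  if (is.null(mtry)) mtry <- max(1L, ceiling(ncol(X) / 3))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  forest <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                       mtry = mtry, nodesize = nodesize)
  structure(list(kind = "rf", forest = forest, oob = forest$predicted,
                 y_train = y,
                 hyper = list(ntree = ntree, mtry = mtry,
                              nodesize = nodesize, seed = seed),
                 bias_correction = NULL),
            class = "sensmap_rf")
}

#' @export
predict.sensmap_rf <- function(object, newdata, ...) {
  raw <- as.numeric(stats::predict(object$forest, as.matrix(newdata)))
  bc <- object$bias_correction
  if (is.null(bc)) raw else bc[2] + bc[1] * raw
}

#' @export
print.sensmap_rf <- function(x, ...) {
  cat("sensmap", toupper(x$kind), "regressor:", x$hyper$ntree, "trees, mtry",
      x$hyper$mtry, "\n")
  if (!is.null(x$bias_correction))
    cat("  bias correction: slope", format(x$bias_correction[1], digits = 4),
        "intercept", format(x$bias_correction[2], digits = 4), "\n")
  invisible(x)
}

#' Bias-corrected random forest (BC-RF)
#'
#' Random-forest regression systematically compresses predictions toward the
#' response mean.  BC-RF fits the forest, then regresses the training
#' response on the out-of-bag predictions with a simple linear model; the
#' stored \code{(slope, intercept)} pair is applied to every raw forest
#' output at prediction time, restoring the dynamic range.
#'
#' @inheritParams fit_rf
#' @return a \code{"sensmap_rf"} object with \code{kind = "bcrf"} and a
#'   non-\code{NULL} \code{bias_correction = c(slope, intercept)}.
#' @export
fit_bcrf <- function(X, y, ntree = 500L, mtry = NULL, nodesize = 5L, seed = 1L) {
  handle <- fit_rf(X, y, ntree = ntree, mtry = mtry,
                   nodesize = nodesize, seed = seed)
  oob <- handle$oob
  if (stats::sd(oob) < 1e-12 || anyNA(oob)) {
    warning("degenerate out-of-bag variance: identity bias correction",
            call. = FALSE)
    corr <- c(1, 0)
  } else {
    cf <- recon_fit(as.numeric(y), oob)   # y ~ [1, oob]
    corr <- c(cf[2], cf[1])               # (slope, intercept)
  }
  handle$kind <- "bcrf"
  handle$bias_correction <- unname(corr)
  handle
}

#' RReliefF feature ranking for a continuous response
#'
#' Regression ReliefF: features are weighted by how much their value
#' differences track response differences among nearest neighbors, estimated
#' from all instances (no sampling, hence deterministic) with
#' distance-weighted neighbor contributions.  Distances and per-feature
#' differences use range-normalized Manhattan metric.
#'
#' @param X numeric matrix, instances x features, no missing values.
#' @param y numeric response.
#' @param n_neighbors neighbors per instance (default 10).
#' @param sigma decay of the rank-based neighbor weights
#'   \code{exp(-(rank/sigma)^2)}.
#' @return a list of class \code{"relieff_ranking"} with \code{ranking}
#'   (feature ids ordered by decreasing weight; ties broken by feature id)
#'   and \code{weights} (named, in input feature order).
#' @export
relieff_rank <- function(X, y, n_neighbors = 10L, sigma = n_neighbors / 2) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X) || anyNA(y)) validation_error("missing values not supported")
  if (n_neighbors >= n) validation_error("n_neighbors must be < number of instances")
  ids <- colnames(X); if (is.null(ids)) ids <- sprintf("f%03d", seq_len(p))

  rngs <- apply(X, 2L, function(col) diff(range(col)))
  rngs[rngs == 0] <- 1          # constant feature: zero diff everywhere
  y_rng <- diff(range(y)); if (y_rng == 0) y_rng <- 1
  Xn <- sweep(X, 2L, rngs, `/`)

  w_rank <- exp(-(seq_len(n_neighbors) / sigma)^2)
  w_rank <- w_rank / sum(w_rank)

  N_dC <- 0
  N_dF <- numeric(p)
  N_dCdF <- numeric(p)
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nb <- setdiff(ord, i)[seq_len(n_neighbors)]
    d_y <- abs(y[i] - y[nb]) / y_rng
    dF <- abs(Xn[rep(i, n_neighbors), , drop = FALSE] -
                Xn[nb, , drop = FALSE])
    N_dC <- N_dC + sum(w_rank * d_y)
    N_dF <- N_dF + drop(crossprod(dF, w_rank))
    N_dCdF <- N_dCdF + drop(crossprod(dF, w_rank * d_y))
  }
  m <- n    # total neighbor weight accumulated (weights sum to 1 per instance)
  weights <- if (N_dC <= 0 || N_dC >= m) rep(0, p)
    else N_dCdF / N_dC - (N_dF - N_dCdF) / (m - N_dC)
  names(weights) <- ids
  ord <- order(-weights, ids)
  structure(list(ranking = ids[ord], weights = weights),
            class = "relieff_ranking")
}

#' Cross-study feature selection by top-k intersection
#'
#' Takes the top \code{k} features of each study's ranking and intersects
#' them, giving a feature set relevant in both studies; ordered by rank in
#' the first ranking.
#'
#' @param rank_a,rank_b ordered feature identifier vectors (best first), or
#'   \code{\link{relieff_rank}} results.
#' @param k depth of each ranking to intersect (200 is the conventional
#'   choice for genome-wide rankings).
#' @return a list of class \code{"feature_selection"} with
#'   \code{target_ranked}, \code{source_ranked}, \code{selected}, \code{k}.
#' @export
select_intersection <- function(rank_a, rank_b, k = 200L) {
  if (inherits(rank_a, "relieff_ranking")) rank_a <- rank_a$ranking
  if (inherits(rank_b, "relieff_ranking")) rank_b <- rank_b$ranking
  if (k > length(rank_a) || k > length(rank_b))
    validation_error("k exceeds a ranking length")
  top_a <- rank_a[seq_len(k)]; top_b <- rank_b[seq_len(k)]
  selected <- top_a[top_a %in% top_b]
  if (length(selected) == 0L)
    abort_sensmap("empty top-k intersection: increase k",
                  "sensmap_empty_selection_error")
  message(length(selected), " feature(s) in the top-", k, " intersection")
  structure(list(target_ranked = rank_a, source_ranked = rank_b,
                 selected = selected, k = as.integer(k)),
            class = "feature_selection")
}
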