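#' Constraint-checked weight vector for the latent combination
#'
#' Weights \code{(c0, c1, c2)} defining the latent signal
#' \code{w = c0 + c1*u1 + c2*u2} from two study vectors, under the box and
#' simplex constraints \code{-1 <= c0 <= 1}, \code{0 <= c1, c2 <= 1},
#' \code{c1 + c2 = 1}.
#'
#' @param c0,c1,c2 numeric scalars.
#' @return a list of class \code{"latent_weights"}.
#' @export
latent_weights <- function(c0, c1, c2) {
  if (abs(c1 + c2 - 1) > 1e-12)
    validation_error("latent weights must satisfy c1 + c2 = 1")
  if (c0 < -1 || c0 > 1 || c1 < 0 || c1 > 1 || c2 < 0 || c2 > 1)
    validation_error("latent weights violate box constraints")
  structure(list(c0 = c0, c1 = c1, c2 = c2), class = "latent_weights")
}

#' Solver settings for the latent cost optimization
#'
#' @param grid_size number of uniform grid points on \code{c1} in
#'   \code{[0, 1]} scanned before local refinement.
#' @param tol convergence tolerance of the bounded scalar refinement.
#' @param denom_floor values of the correlation-sum denominator at or below
#'   this floor mark the point infeasible (cost \code{+Inf}).
#' @return a list of class \code{"solver_config"}.
#' @export
solver_config <- function(grid_size = 1001L, tol = 1e-10, denom_floor = 1e-8) {
  if (grid_size < 2L) validation_error("grid_size must be >= 2")
  structure(list(grid_size = as.integer(grid_size), tol = tol,
                 denom_floor = denom_floor), class = "solver_config")
}

# least-squares reconstruction coefficients of u from the design [1 w]
recon_fit <- function(u, w) {
  stats::lm.fit(cbind(1, w), u)$coefficients
}

# Vectorized ratio cost over a grid of t = c1 values (c0 = 0, c2 = 1 - t),
# using the moment identities: the residual SSE of regressing u on [1, w]
# is (n-1) var(u) (1 - cor(u, w)^2).  Algebraically identical to
# ratio_cost(); used by the solver for speed.
ratio_cost_curve <- function(u1, u2, ts, denom_floor) {
  n <- length(u1)
  s11 <- stats::var(u1); s22 <- stats::var(u2); s12 <- stats::cov(u1, u2)
  var_w <- ts^2 * s11 + (1 - ts)^2 * s22 + 2 * ts * (1 - ts) * s12
  cov1 <- ts * s11 + (1 - ts) * s12
  cov2 <- ts * s12 + (1 - ts) * s22
  cost <- rep(Inf, length(ts))
  ok <- var_w > 0
  r1 <- r2 <- rep(NA_real_, length(ts))
  r1[ok] <- cov1[ok] / sqrt(s11 * var_w[ok])
  r2[ok] <- cov2[ok] / sqrt(s22 * var_w[ok])
  denom <- r1 + r2
  ok <- ok & is.finite(denom) & denom > denom_floor
  # clamp: 1 - r^2 can round to a tiny negative on exactly collinear data
  sse <- (n - 1) * (s11 * pmax(1 - r1[ok]^2, 0) + s22 * pmax(1 - r2[ok]^2, 0))
  cost[ok] <- sse / denom[ok]
  cost
}

#' Ratio cost of a candidate latent combination
#'
#' The objective driving the latent predictors: the summed squared
#' reconstruction error of both study vectors from the latent design
#' \code{[1 w]} (with the inner least-squares fits profiled out), divided by
#' the sum of the Pearson correlations of each vector with the latent.
#' Small cost means both vectors are reconstructed well from a latent that is
#' strongly positively concordant with each of them.
#'
#' @param u1,u2 equal-length numeric vectors (length >= 3, non-constant).
#' @param weights a \code{\link{latent_weights}} object.
#' @param solver_cfg a \code{\link{solver_config}} (only the denominator
#'   floor is used here).
#' @return the objective value; \code{+Inf} when the latent is (nearly)
#'   constant or the correlation sum does not exceed the floor.
#' @export
ratio_cost <- function(u1, u2, weights, solver_cfg = solver_config()) {
  u1 <- as.numeric(u1); u2 <- as.numeric(u2)
  if (length(u1) != length(u2)) alignment_error("u1 and u2 lengths differ")
  if (length(u1) < 3L) validation_error("need at least 3 observations")
  if (stats::sd(u1) == 0 || stats::sd(u2) == 0)
    degenerate_error("constant input vector: correlation undefined")
  w <- weights$c0 + weights$c1 * u1 + weights$c2 * u2
  if (stats::sd(w) == 0) return(Inf)
  denom <- stats::cor(u1, w) + stats::cor(u2, w)
  if (!is.finite(denom) || denom <= solver_cfg$denom_floor) return(Inf)
  W <- cbind(1, w)
  r1 <- u1 - W %*% recon_fit(u1, w)
  r2 <- u2 - W %*% recon_fit(u2, w)
  (sum(r1^2) + sum(r2^2)) / denom
}

#' Minimize the ratio cost over the feasible weight set
#'
#' The objective is flat in the offset \code{c0} (the latent design carries an
#' intercept column and Pearson correlation is shift-invariant), so \code{c0}
#' is fixed at 0 and the search is one-dimensional over \code{t = c1} in
#' \code{[0, 1]} with \code{c2 = 1 - t}: a dense uniform grid scan followed by
#' bounded scalar refinement around the best grid point.  On flat stretches of
#' the objective the tie-break returns the feasible \code{t} closest to 0.5
#' (equal weighting of the two studies).
#'
#' @param u1,u2 the two study vectors over the training cells.
#' @param solver_cfg a \code{\link{solver_config}}.
#' @return a list of class \code{"latent_model"} with components
#'   \code{weights} (\code{\link{latent_weights}}), \code{w_train} (the
#'   optimized latent over the training cells), \code{a1}, \code{a2} (the
#'   reconstruction coefficient pairs for \code{u1} and \code{u2}),
#'   \code{cost} (achieved objective), and \code{b2 = NULL} (filled by
#'   \code{\link{fit_latent_regression}} when needed).
#' @export
optimize_latent <- function(u1, u2, solver_cfg = solver_config()) {
  u1 <- as.numeric(u1); u2 <- as.numeric(u2)
  if (length(u1) != length(u2)) alignment_error("u1 and u2 lengths differ")
  if (length(u1) < 3L) validation_error("need at least 3 observations")
  if (stats::sd(u1) == 0 || stats::sd(u2) == 0)
    degenerate_error("constant input vector: correlation undefined")
  ts <- seq(0, 1, length.out = solver_cfg$grid_size)
  costs <- ratio_cost_curve(u1, u2, ts, solver_cfg$denom_floor)
  if (all(!is.finite(costs)))
    optimization_error("all grid points infeasible: the two vectors are not positively concordant with any convex latent combination")
  cmin <- min(costs)
  # flat-objective tie-break: among (numerically) minimal grid points take
  # the one closest to equal weighting
  flat <- which(costs <= cmin + 1e-12 * max(1, abs(cmin)))
  t_best <- ts[flat[which.min(abs(ts[flat] - 0.5))]]
  c_best <- costs[which(ts == t_best)]

  h <- 1 / (solver_cfg$grid_size - 1)
  ref <- stats::optimize(function(t)
    ratio_cost_curve(u1, u2, t, solver_cfg$denom_floor),
    lower = max(0, t_best - h), upper = min(1, t_best + h),
    tol = solver_cfg$tol)
  # accept refinement only on a beyond-roundoff improvement, so the 0.5
  # tie-break survives on flat objectives
  if (is.finite(ref$objective) &&
      c_best - ref$objective > 1e-12 * max(1, abs(c_best))) {
    t_best <- ref$minimum
    c_best <- ref$objective
  }

  wts <- latent_weights(0, t_best, 1 - t_best)
  w <- wts$c1 * u1 + wts$c2 * u2
  model <- list(weights = wts, w_train = w,
                a1 = unname(recon_fit(u1, w)), a2 = unname(recon_fit(u2, w)),
                b2 = NULL, cost = c_best)
  class(model) <- "latent_model"
  model
}

#' @export
print.latent_model <- function(x, ...) {
  cat("Latent sensitivity model: c1 =", format(x$weights$c1, digits = 4),
      "cost =", format(x$cost, digits = 4), "\n")
  invisible(x)
}

#' Affine regression of the latent on the source sensitivity
#'
#' Fits \code{w ~ [1 y_source]} by the Moore-Penrose pseudoinverse, giving
#' the coefficients used to infer the latent for cells whose target response
#' is unknown but whose source response is measured.
#'
#' @param y_source source-study AUC over the training cells.
#' @param w latent vector over the same cells.
#' @return the coefficient 2-vector \code{(intercept, slope)}.
#' @export
fit_latent_regression <- function(y_source, w) {
  y_source <- as.numeric(y_source); w <- as.numeric(w)
  if (length(y_source) != length(w)) alignment_error("lengths differ")
  if (length(w) < 2L) validation_error("need at least 2 observations")
  if (stats::sd(y_source) == 0)
    warning("constant source AUC: rank-deficient design handled by pseudoinverse",
            call. = FALSE)
  drop(MASS::ginv(cbind(1, y_source)) %*% w)
}

# shared guard: predictors needing matched source AUC for prediction cells
check_matched <- function(y22, method) {
  if (length(y22) == 0L)
    applicability_error(paste0(method, " requires matched source AUC for the prediction cells (none supplied); use a predictor applicable to unmatched pairs instead"))
  if (anyNA(y22))
    applicability_error(paste0(method, " requires matched source AUC for every prediction cell; ", sum(is.na(y22)), " cell(s) lack a source measurement"))
  invisible(TRUE)
}

#' Latent Regression Prediction (LRP)
#'
#' Predicts unknown target-study AUC from source-study AUC alone: the latent
#' is optimized on the training pairs, regressed on the source response, then
#' inferred for the prediction cells from their (matched, required) source
#' response and mapped to the target scale through the stored reconstruction
#' coefficients.
#'
#' @param y11 target AUC over training cells.
#' @param y21 source AUC over the same training cells.
#' @param y22 source AUC over the prediction cells (must be fully observed).
#' @param solver_cfg a \code{\link{solver_config}}.
#' @return a list with \code{pred} (predicted target AUC over the prediction
#'   cells, a \code{\link{sensitivity_vector}} when \code{y22} is one),
#'   \code{model} (the fitted \code{latent_model}, with \code{b2} filled) and
#'   \code{w2} (the inferred latent for the prediction cells).
#' @export
lrp_predict <- function(y11, y21, y22, solver_cfg = solver_config()) {
  check_matched(y22, "LRP")
  if (anyNA(y11) || anyNA(y21))
    applicability_error("LRP training requires observed AUC in both studies")
  model <- optimize_latent(as.numeric(y11), as.numeric(y21), solver_cfg)
  model$b2 <- fit_latent_regression(as.numeric(y21), model$w_train)
  w2 <- drop(cbind(1, as.numeric(y22)) %*% model$b2)
  yhat <- drop(cbind(1, w2) %*% model$a1)
  pred <- if (inherits(y22, "sensitivity_vector"))
    suppressWarnings(sensitivity_vector(yhat, names(y22),
                                        drug_id = attr(y22, "drug_id")))
  else yhat
  list(pred = pred, model = model, w2 = w2)
}

#' Per-gene latent matrix across the two studies
#'
#' Runs the same constrained ratio-cost optimization gene by gene on the
#' paired expression columns and concatenates the optimized latent vectors
#' into an n x p matrix.  A gene whose optimization is degenerate (either
#' column constant) falls back to the standardized mean of its two columns
#' and is flagged.
#'
#' @param X1,X2 matched \code{\link{expression_matrix}} objects (target,
#'   source), identical dimensions and ids.
#' @param solver_cfg a \code{\link{solver_config}}.
#' @return a list of class \code{"gene_latent_matrix"}: \code{V} (n x p
#'   latent matrix), \code{lambdas} (3 x p weight matrix), \code{alphas}
#'   (list of per-gene reconstruction coefficient pairs), \code{costs},
#'   \code{degenerate} (logical flags).
#' @export
build_gene_latents <- function(X1, X2, solver_cfg = solver_config()) {
  if (!identical(dim(X1), dim(X2)) ||
      !identical(colnames(X1), colnames(X2)) ||
      !identical(rownames(X1), rownames(X2)))
    alignment_error("expression matrices are not matched")
  n <- nrow(X1); p <- ncol(X1)
  V <- matrix(NA_real_, n, p, dimnames = dimnames(X1))
  lambdas <- matrix(NA_real_, 3L, p, dimnames = list(c("c0", "c1", "c2"), colnames(X1)))
  alphas <- vector("list", p); names(alphas) <- colnames(X1)
  costs <- rep(NA_real_, p); degen <- rep(FALSE, p)
  for (k in seq_len(p)) {
    x1 <- X1[, k]; x2 <- X2[, k]
    if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
      m <- (x1 + x2) / 2
      V[, k] <- if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else rep(0, n)
      degen[k] <- TRUE
      next
    }
    fit <- optimize_latent(x1, x2, solver_cfg)
    V[, k] <- fit$w_train
    lambdas[, k] <- c(fit$weights$c0, fit$weights$c1, fit$weights$c2)
    alphas[[k]] <- list(a1 = fit$a1, a2 = fit$a2)
    costs[k] <- fit$cost
  }
  if (any(degen))
    message(sum(degen), " gene(s) with a constant column: standardized-mean latent fallback used")
  structure(list(V = V, lambdas = lambdas, alphas = alphas, costs = costs,
                 degenerate = degen), class = "gene_latent_matrix")
}

check_train_idx <- function(train_idx, n) {
  train_idx <- as.integer(train_idx)
  if (length(train_idx) == 0L) validation_error("empty training index set")
  if (anyDuplicated(train_idx) || any(train_idx < 1L) || any(train_idx > n))
    validation_error("training indices out of range or duplicated")
  if (length(train_idx) >= n)
    validation_error("training set covers all cells: nothing to predict")
  if (length(train_idx) < 10L)
    warning("fewer than 10 training cells", call. = FALSE)
  train_idx
}

# normalize a regressor argument into fit/predict closures
as_regressor <- function(regressor) {
  if (is.null(regressor)) regressor <- function(X, y) fit_rf(X, y)
  function(X, y) {
    fitted <- regressor(X, y)
    if (is.function(fitted)) fitted else function(newX) stats::predict(fitted, newX)
  }
}

#' Latent-Latent Prediction (LLP)
#'
#' Predicts target AUC from expression: the sensitivity latent \code{w1} is
#' optimized on the training AUC pairs, a per-gene latent matrix \code{V} is
#' built from the two expression matrices, a regressor (random forest by
#' default) learns \code{V[train] -> w1}, the latent for the remaining cells
#' is predicted from \code{V[test]}, and target AUC follows from the stored
#' reconstruction coefficients.  Unlike LRP, prediction does not need the
#' source AUC of the prediction cells.
#'
#' @param study a \code{\link{pair_studies}} object.
#' @param train_idx integer indices of the training cells.
#' @param regressor \code{NULL} for the default random forest, or a function
#'   \code{f(X, y)} returning either an object with a \code{predict} method
#'   or a prediction function \code{g(newX)}.
#' @param solver_cfg a \code{\link{solver_config}}.
#' @return a list with \code{pred} (predicted target AUC over the
#'   non-training cells), \code{w2} (predicted latent), \code{model} (the
#'   sensitivity \code{latent_model}) and \code{gene_latents}.
#' @export
llp_predict <- function(study, train_idx, regressor = NULL,
                        solver_cfg = solver_config()) {
  n <- nrow(study$target_expr)
  train_idx <- check_train_idx(train_idx, n)
  test_idx <- setdiff(seq_len(n), train_idx)
  y11 <- sens_values(study$target_auc)[train_idx]
  y21 <- sens_values(study$source_auc)[train_idx]
  if (anyNA(y11) || anyNA(y21))
    applicability_error("LLP training requires observed AUC in both studies for the training cells")
  model <- optimize_latent(y11, y21, solver_cfg)
  gl <- build_gene_latents(study$target_expr, study$source_expr, solver_cfg)
  fit <- as_regressor(regressor)(gl$V[train_idx, , drop = FALSE], model$w_train)
  w2 <- as.numeric(fit(gl$V[test_idx, , drop = FALSE]))
  yhat <- drop(cbind(1, w2) %*% model$a1)
  pred <- suppressWarnings(sensitivity_vector(
    yhat, rownames(study$target_expr)[test_idx],
    drug_id = attr(study$target_auc, "drug_id")))
  list(pred = pred, w2 = w2, model = model, gene_latents = gl)
}

#' Combined Latent Prediction (CLP)
#'
#' Averages the latent predicted by LRP (from matched source AUC) and by LLP
#' (from the expression latents) for each prediction cell, then maps the
#' averaged latent to the target AUC scale.  Both arms share a single cost
#' optimization, hence the same reconstruction coefficients.  Requires
#' matched source AUC for the prediction cells, like LRP.
#'
#' @inheritParams llp_predict
#' @return a list with \code{pred}, \code{w2} (averaged latent),
#'   \code{w2_lrp}, \code{w2_llp} and \code{model}.
#' @export
clp_predict <- function(study, train_idx, regressor = NULL,
                        solver_cfg = solver_config()) {
  n <- nrow(study$target_expr)
  train_idx <- check_train_idx(train_idx, n)
  test_idx <- setdiff(seq_len(n), train_idx)
  y22 <- sens_values(study$source_auc)[test_idx]
  check_matched(y22, "CLP")
  y11 <- sens_values(study$target_auc)[train_idx]
  y21 <- sens_values(study$source_auc)[train_idx]
  if (anyNA(y11) || anyNA(y21))
    applicability_error("CLP training requires observed AUC in both studies")

  model <- optimize_latent(y11, y21, solver_cfg)
  model$b2 <- fit_latent_regression(y21, model$w_train)
  w2_lrp <- drop(cbind(1, y22) %*% model$b2)

  gl <- build_gene_latents(study$target_expr, study$source_expr, solver_cfg)
  fit <- as_regressor(regressor)(gl$V[train_idx, , drop = FALSE], model$w_train)
  w2_llp <- as.numeric(fit(gl$V[test_idx, , drop = FALSE]))

  w2 <- (w2_lrp + w2_llp) / 2
  yhat <- drop(cbind(1, w2) %*% model$a1)
  pred <- suppressWarnings(sensitivity_vector(
    yhat, rownames(study$target_expr)[test_idx],
    drug_id = attr(study$target_auc, "drug_id")))
  list(pred = pred, w2 = w2, w2_lrp = w2_lrp, w2_llp = w2_llp, model = model)
}
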