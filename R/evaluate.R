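#' Build the train-on-one-fold evaluation scheme
#'
#' Partitions \code{n} cells into \code{K = floor(n / train_fold_size)}
#' near-equal random folds.  The protocol inverts the usual cross-validation
#' orientation: each fold in turn is the (small) training set and the union
#' of the remaining \code{K - 1} folds is the test set, emulating a target
#' study where only ~50 labeled cell lines are available at a time.
#'
#' @param n number of cells (must be at least \code{2 * train_fold_size} so
#'   there is something to test).
#' @param train_fold_size nominal fold size (default 50).
#' @param seed integer seed for the permutation.
#' @return a list of class \code{"fold_scheme"}: \code{n}, \code{K},
#'   \code{folds} (list of disjoint index vectors covering \code{1:n}),
#'   \code{train_fold_size}, \code{seed}.
#' @export
make_folds <- function(n, train_fold_size = 50L, seed = 1L) {
  n <- as.integer(n); train_fold_size <- as.integer(train_fold_size)
  if (n < 2L * train_fold_size)
    validation_error("n must be at least twice the training fold size")
  K <- n %/% train_fold_size
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  perm <- sample.int(n)
  base <- n %/% K; rem <- n %% K
  sizes <- rep(base, K) + c(rep(1L, rem), rep(0L, K - rem))
  folds <- split(perm, rep(seq_len(K), times = sizes))
  names(folds) <- NULL
  structure(list(n = n, K = K, folds = folds,
                 train_fold_size = train_fold_size, seed = seed),
            class = "fold_scheme")
}

#' Evaluation metrics
#'
#' Pearson and Spearman correlation, mean squared error, and NRMSE defined
#' as RMSE divided by the range of the true values (a recorded convention;
#' the normalization is stated in every report).
#'
#' @param a,b,truth,pred equal-length numeric vectors.
#' @return a single number.
#' @export
pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3L)
    validation_error("need equal lengths >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    degenerate_error("constant input to correlation")
  stats::cor(a, b)
}

#' @rdname pearson
#' @export
spearman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3L)
    validation_error("need equal lengths >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    degenerate_error("constant input to correlation")
  stats::cor(a, b, method = "spearman")
}

#' @rdname pearson
#' @export
mse <- function(truth, pred) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  if (length(truth) != length(pred)) validation_error("lengths differ")
  mean((truth - pred)^2)
}

#' @rdname pearson
#' @export
nrmse <- function(truth, pred) {
  truth <- as.numeric(truth)
  rng <- diff(range(truth))
  if (rng == 0) degenerate_error("constant truth: range normalization undefined")
  sqrt(mse(truth, pred)) / rng
}

#' Direct Prediction (DP) baseline
#'
#' Trains on the labeled target cells only and predicts the rest; no source
#' data involved.
#'
#' @param study a \code{\link{pair_studies}} object.
#' @param train_idx labeled target cell indices.
#' @param model as in \code{\link{mapped_prediction}}.
#' @return predicted target AUC over the non-training cells.
#' @export
direct_prediction <- function(study, train_idx, model = NULL) {
  n <- nrow(study$target_expr)
  train_idx <- check_train_idx(train_idx, n)
  test_idx <- setdiff(seq_len(n), train_idx)
  y1 <- sens_values(study$target_auc)
  if (anyNA(y1[train_idx]))
    applicability_error("training cells must have observed target AUC")
  fit <- as_regressor(resolve_model(model))(
    unclass(study$target_expr)[train_idx, , drop = FALSE], y1[train_idx])
  yhat <- as.numeric(fit(unclass(study$target_expr)[test_idx, , drop = FALSE]))
  suppressWarnings(sensitivity_vector(yhat, rownames(study$target_expr)[test_idx],
                                      drug_id = attr(study$target_auc, "drug_id")))
}

#' Source-model prediction (CP) baseline
#'
#' Trains on the full source study and predicts target cells from their raw
#' (unmapped) target-space expression — the cross-study baseline that
#' ignores the distribution shift between studies.
#'
#' @inheritParams direct_prediction
#' @export
ccle_model_prediction <- function(study, train_idx, model = NULL) {
  n <- nrow(study$target_expr)
  train_idx <- check_train_idx(train_idx, n)
  test_idx <- setdiff(seq_len(n), train_idx)
  y2 <- sens_values(study$source_auc)
  if (length(y2) == 0L || anyNA(y2))
    applicability_error("source-model prediction requires the full source AUC vector")
  fit <- as_regressor(resolve_model(model))(unclass(study$source_expr), y2)
  yhat <- as.numeric(fit(unclass(study$target_expr)[test_idx, , drop = FALSE]))
  suppressWarnings(sensitivity_vector(yhat, rownames(study$target_expr)[test_idx],
                                      drug_id = attr(study$target_auc, "drug_id")))
}

#' Combined Model Prediction (CMP) baseline
#'
#' Trains a single model on the row-concatenation of the full source study
#' and the labeled target cells, then predicts the unlabeled target cells.
#' With no source rows it reduces to DP; with no labeled target rows to CP.
#'
#' @inheritParams direct_prediction
#' @param include_source if \code{FALSE} the source block is omitted
#'   (reduction check).
#' @export
combined_model_prediction <- function(study, train_idx, model = NULL,
                                      include_source = TRUE) {
  n <- nrow(study$target_expr)
  train_idx <- check_train_idx(train_idx, n)
  test_idx <- setdiff(seq_len(n), train_idx)
  y1 <- sens_values(study$target_auc); y2 <- sens_values(study$source_auc)
  if (anyNA(y1[train_idx]))
    applicability_error("training cells must have observed target AUC")
  Xtr <- unclass(study$target_expr)[train_idx, , drop = FALSE]
  ytr <- y1[train_idx]
  if (include_source) {
    if (anyNA(y2)) applicability_error("combined model requires the full source AUC vector")
    Xtr <- rbind(unclass(study$source_expr), Xtr)
    ytr <- c(y2, ytr)
  }
  fit <- as_regressor(resolve_model(model))(Xtr, ytr)
  yhat <- as.numeric(fit(unclass(study$target_expr)[test_idx, , drop = FALSE]))
  suppressWarnings(sensitivity_vector(yhat, rownames(study$target_expr)[test_idx],
                                      drug_id = attr(study$target_auc, "drug_id")))
}

# map a model spec ("rf"/"bcrf"/NULL/function) to a fitting function
resolve_model <- function(model) {
  if (is.null(model) || identical(model, "bcrf")) return(function(X, y) fit_bcrf(X, y))
  if (identical(model, "rf")) return(function(X, y) fit_rf(X, y))
  model
}

benchmark_methods <- c("LRP", "LLP", "CLP", "MP", "DP", "CP", "CMP")

# run one method on one fold; returns numeric predictions for the test cells
run_method <- function(method, study, train_idx, model, solver_cfg) {
  n <- nrow(study$target_expr)
  test_idx <- setdiff(seq_len(n), train_idx)
  y1 <- sens_values(study$target_auc); y2 <- sens_values(study$source_auc)
  switch(method,
    LRP = lrp_predict(
      sensitivity_vector(y1[train_idx], allow_na = TRUE),
      sensitivity_vector(y2[train_idx], allow_na = TRUE),
      sensitivity_vector(y2[test_idx], allow_na = TRUE),
      solver_cfg)$pred,
    LLP = llp_predict(study, train_idx, model, solver_cfg)$pred,
    CLP = clp_predict(study, train_idx, model, solver_cfg)$pred,
    MP  = mapped_prediction(study, train_idx, model)$pred,
    DP  = direct_prediction(study, train_idx, model),
    CP  = ccle_model_prediction(study, train_idx, model),
    CMP = combined_model_prediction(study, train_idx, model),
    validation_error(paste("unknown method:", method)))
}

#' Run the benchmark protocol over all folds and methods
#'
#' For each fold of the scheme, each method trains on that fold and predicts
#' the union of the remaining folds; Pearson correlation and NRMSE against
#' the held-out target AUC are recorded per fold and averaged.  Methods not
#' applicable to the study (e.g. LRP without matched source AUC for the
#' prediction cells) are skipped with the reason logged in the report.
#'
#' @param study a \code{\link{pair_studies}} object.
#' @param methods character vector among
#'   \code{c("LRP","LLP","CLP","MP","DP","CP","CMP")}.
#' @param fold_scheme a \code{\link{make_folds}} result.
#' @param model regressor specification passed to the methods that take one.
#' @param solver_cfg a \code{\link{solver_config}} for the latent methods.
#' @return a list of class \code{"eval_report"}: \code{per_fold} (data frame
#'   method/fold/pearson/nrmse), \code{summary} (per-method means),
#'   \code{skipped} (named reasons), \code{nrmse_normalization}, \code{seed}.
#' @export
run_benchmark <- function(study, methods = c("DP", "MP"), fold_scheme,
                          model = NULL, solver_cfg = solver_config()) {
  methods <- match.arg(methods, benchmark_methods, several.ok = TRUE)
  y1 <- sens_values(study$target_auc)
  rows <- list(); skipped <- character(0)
  for (m in methods) {
    for (k in seq_len(fold_scheme$K)) {
      train_idx <- fold_scheme$folds[[k]]
      test_idx <- setdiff(seq_len(fold_scheme$n), train_idx)
      res <- tryCatch(
        run_method(m, study, train_idx, model, solver_cfg),
        sensmap_applicability_error = function(e) e)
      if (inherits(res, "condition")) {
        skipped[m] <- conditionMessage(res)
        break
      }
      truth <- y1[test_idx]
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, fold = k,
        pearson = pearson(truth, res),
        nrmse = nrmse(truth, res))
    }
  }
  per_fold <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(), fold = integer(),
               pearson = numeric(), nrmse = numeric())
  per_fold <- per_fold[!(per_fold$method %in% names(skipped)), , drop = FALSE]
  summary <- if (nrow(per_fold)) {
    agg <- stats::aggregate(cbind(pearson, nrmse) ~ method, data = per_fold, FUN = mean)
    agg[match(intersect(methods, agg$method), agg$method), , drop = FALSE]
  } else data.frame(method = character(), pearson = numeric(), nrmse = numeric())
  structure(list(per_fold = per_fold, summary = summary, skipped = skipped,
                 nrmse_normalization = "range of true test values",
                 drug_id = attr(study$target_auc, "drug_id"),
                 seed = fold_scheme$seed,
                 train_fold_size = fold_scheme$train_fold_size),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Benchmark report (drug:", x$drug_id, "| K =",
      length(unique(x$per_fold$fold)), "folds, train fold ~",
      x$train_fold_size, "cells)\n")
  cat("NRMSE normalization:", x$nrmse_normalization, "\n")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  if (length(x$skipped))
    cat("Skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  invisible(x)
}
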