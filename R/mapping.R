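#' Fit the gene-wise first-order cross-study expression map
#'
#' For each gene, ordinary least squares of the destination column on
#' \code{[1, source column]}; the per-gene intercepts and slopes are the
#' diagonals of the affine map applied column-wise by
#' \code{\link{apply_gene_map}}.  The direction is explicit in the call: the
#' Mapped Prediction pipeline fits target-space expression onto source-space
#' expression.
#'
#' @param G_from,G_to matched \code{\link{expression_matrix}} objects with
#'   identical cell and gene ids; the map sends \code{G_from}-space columns
#'   toward \code{G_to}-space.
#' @return a list of class \code{"gene_map"}: \code{intercepts},
#'   \code{slopes}, \code{gene_ids}, \code{fit_mse} (per-gene training MSE),
#'   and \code{spearman} (per-gene rank correlation between the paired
#'   columns, a diagnostic for the adequacy of a first-order map).
#' @export
fit_gene_map <- function(G_from, G_to) {
  if (!identical(dim(G_from), dim(G_to)) ||
      !identical(colnames(G_from), colnames(G_to)) ||
      !identical(rownames(G_from), rownames(G_to)))
    alignment_error("expression matrices are not matched")
  if (nrow(G_from) < 3L) insufficient_data_error("need at least 3 cell lines to fit the gene map")
  p <- ncol(G_from)
  intercepts <- slopes <- fit_mse <- rho_s <- rep(NA_real_, p)
  const <- logical(p)
  for (i in seq_len(p)) {
    x <- G_from[, i]; y <- G_to[, i]
    if (stats::sd(x) == 0) {
      const[i] <- TRUE
      slopes[i] <- 0; intercepts[i] <- mean(y)
      fit_mse[i] <- mean((y - intercepts[i])^2)
      next
    }
    cf <- recon_fit(y, x)
    intercepts[i] <- cf[1]; slopes[i] <- cf[2]
    fit_mse[i] <- mean((y - cf[1] - cf[2] * x)^2)
    rho_s[i] <- if (stats::sd(y) > 0)
      stats::cor(x, y, method = "spearman") else NA_real_
  }
  if (any(const))
    warning(sum(const), " constant gene column(s): slope 0, intercept = mean",
            call. = FALSE)
  structure(list(intercepts = stats::setNames(intercepts, colnames(G_from)),
                 slopes = stats::setNames(slopes, colnames(G_from)),
                 gene_ids = colnames(G_from),
                 fit_mse = stats::setNames(fit_mse, colnames(G_from)),
                 spearman = stats::setNames(rho_s, colnames(G_from))),
            class = "gene_map")
}

#' Apply a fitted gene map column-wise
#'
#' @param G an \code{\link{expression_matrix}} whose gene ids match the map.
#' @param map a \code{\link{fit_gene_map}} result.
#' @return the mapped matrix, same shape and ids.
#' @export
apply_gene_map <- function(G, map) {
  if (!identical(colnames(G), map$gene_ids))
    alignment_error("gene ids do not match the fitted map")
  out <- sweep(sweep(unclass(G), 2L, map$slopes, `*`), 2L, map$intercepts, `+`)
  expression_matrix(out)
}

#' Fit the drug-wise second-order cross-study sensitivity map
#'
#' Least-squares fit of the destination AUC on \code{[1, d, d^2]} of the
#' origin AUC.  The pipeline direction is source-space AUC onto target-space
#' AUC.  A warning is emitted when the fitted parabola's vertex lies inside
#' the observed origin range, i.e. the map is non-monotone over the data —
#' at odds with the assumption that the two studies' responses move in the
#' same direction.
#'
#' @param d_from origin AUC (\code{\link{sensitivity_vector}} or numeric).
#' @param d_to destination AUC over the same cells.
#' @return a list of class \code{"drug_map"}: \code{beta} (3-vector for the
#'   design \code{[1, d, d^2]}), \code{drug_id}, \code{fit_mse},
#'   \code{spearman} (rank correlation diagnostic).
#' @export
fit_drug_map <- function(d_from, d_to) {
  x <- as.numeric(d_from); y <- as.numeric(d_to)
  if (length(x) != length(y)) alignment_error("AUC vectors are not matched")
  if (length(x) < 4L)
    insufficient_data_error("need at least 4 cell lines for the quadratic map")
  if (stats::sd(x) == 0) degenerate_error("constant origin AUC: collinear design")
  D <- cbind(1, x, x^2)
  beta <- unname(stats::lm.fit(D, y)$coefficients)
  if (anyNA(beta)) degenerate_error("rank-deficient quadratic design")
  mse <- mean((y - drop(D %*% beta))^2)
  if (abs(beta[3]) > 0) {
    vertex <- -beta[2] / (2 * beta[3])
    if (vertex > min(x) && vertex < max(x))
      warning("fitted quadratic is non-monotone over the observed AUC range",
              call. = FALSE)
  }
  drug <- attr(d_to, "drug_id")
  structure(list(beta = beta,
                 drug_id = if (is.null(drug)) "drug" else drug,
                 fit_mse = mse,
                 spearman = if (stats::sd(y) > 0)
                   stats::cor(x, y, method = "spearman") else NA_real_),
            class = "drug_map")
}

#' Apply a fitted drug map
#'
#' @param d AUC values to map.
#' @param map a \code{\link{fit_drug_map}} result.
#' @return mapped values, \code{b0 + b1 d + b2 d^2}; values outside
#'   \code{[0, 1]} are reported via message but not clipped.
#' @export
apply_drug_map <- function(d, map) {
  x <- as.numeric(d)
  if (any(!is.finite(x))) validation_error("non-finite AUC input")
  out <- map$beta[1] + map$beta[2] * x + map$beta[3] * x^2
  n_out <- sum(out < 0 | out > 1)
  if (n_out > 0)
    message(n_out, " mapped AUC value(s) outside [0, 1]; not clipped")
  if (inherits(d, "sensitivity_vector"))
    suppressWarnings(sensitivity_vector(out, names(d), drug_id = map$drug_id))
  else out
}

#' Mapped Prediction (MP): domain-transfer drug sensitivity prediction
#'
#' Transfers the target study into source space and back: the gene map is
#' fitted target-to-source on the labeled training cells, the drug map
#' source-to-target on the same cells; the unlabeled target expression is
#' mapped into source space, scored by a model trained on the full source
#' study (bias-corrected random forest by default), and the source-space
#' prediction is mapped back to the target AUC scale.
#'
#' @param study a \code{\link{pair_studies}} object.
#' @param train_idx indices of the labeled target cells (>= 4, needed for the
#'   quadratic drug map; a 50-cell subset is the conventional setting).
#' @param model \code{NULL} for the default bias-corrected random forest,
#'   \code{"rf"} or \code{"bcrf"}, or a fitting function as in
#'   \code{\link{llp_predict}}.
#' @param gene_map_cells \code{"train"} (default) fits the expression map on
#'   the training cells only; \code{"all"} uses every matched cell, exploiting
#'   expression available for unlabeled cells.
#' @return a list with \code{pred} (predicted target AUC over the
#'   non-training cells), \code{gene_map}, \code{drug_map},
#'   \code{d22} (source-space predictions before the drug map), and
#'   \code{diagnostics} (rank-correlation summaries of both maps).
#' @export
mapped_prediction <- function(study, train_idx, model = NULL,
                              gene_map_cells = c("train", "all")) {
  gene_map_cells <- match.arg(gene_map_cells)
  n <- nrow(study$target_expr)
  train_idx <- as.integer(train_idx)
  if (length(train_idx) < 4L)
    insufficient_data_error("Mapped Prediction needs at least 4 training cells for the quadratic drug map")
  train_idx <- check_train_idx(train_idx, n)
  test_idx <- setdiff(seq_len(n), train_idx)

  y1 <- sens_values(study$target_auc); y2 <- sens_values(study$source_auc)
  if (anyNA(y1[train_idx]) || anyNA(y2[train_idx]))
    applicability_error("training cells must have observed AUC in both studies")
  if (anyNA(y2))
    applicability_error("Mapped Prediction trains its source model on the full source AUC vector")

  map_rows <- if (gene_map_cells == "train") train_idx else seq_len(n)
  h <- fit_gene_map(
    expression_matrix(unclass(study$target_expr)[map_rows, , drop = FALSE]),
    expression_matrix(unclass(study$source_expr)[map_rows, , drop = FALSE]))
  f <- fit_drug_map(y2[train_idx], sensitivity_vector(
    y1[train_idx], names(y1)[train_idx],
    drug_id = attr(study$target_auc, "drug_id")))

  G22_hat <- apply_gene_map(
    expression_matrix(unclass(study$target_expr)[test_idx, , drop = FALSE]), h)

  fit_fun <- if (is.null(model) || identical(model, "bcrf")) {
    function(X, y) fit_bcrf(X, y)
  } else if (identical(model, "rf")) {
    function(X, y) fit_rf(X, y)
  } else model
  fitted <- as_regressor(fit_fun)(unclass(study$source_expr), y2)
  d22_hat <- as.numeric(fitted(unclass(G22_hat)))
  pred <- suppressWarnings(sensitivity_vector(
    apply_drug_map(d22_hat, f), rownames(G22_hat),
    drug_id = attr(study$target_auc, "drug_id")))
  list(pred = pred, gene_map = h, drug_map = f, d22 = d22_hat,
       diagnostics = list(
         gene_map_spearman_median = stats::median(h$spearman, na.rm = TRUE),
         drug_map_spearman = f$spearman))
}
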