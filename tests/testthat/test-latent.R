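test_that("ratio cost matches its closed collinear and degenerate cases", {
  # collinear inputs: latent is affine in the common vector, reconstruction
  # exact, both correlations 1
  w <- latent_weights(0, 0.3, 0.7)
  expect_equal(ratio_cost(c(1, 2, 3, 4), c(1, 2, 3, 4), w), 0, tolerance = 1e-12)

  # anti-parallel inputs at equal weights: latent constant, denominator floor
  expect_identical(ratio_cost(c(1, 2, 3), c(3, 2, 1), latent_weights(0, 0.5, 0.5)),
                   Inf)

  expect_error(ratio_cost(rep(1, 5), c(1, 2, 3, 4, 5), w),
               class = "sensmap_degenerate_error")
  expect_error(latent_weights(0, 0.6, 0.6), class = "sensmap_validation_error")
  expect_error(latent_weights(2, 0.5, 0.5), class = "sensmap_validation_error")
})

test_that("ratio cost agrees with an independently coded evaluation", {
  # independent route: explicit lm() fits and cor() calls, no shared algebra
  oracle <- function(u1, u2, c0, c1, c2) {
    w <- c0 + c1 * u1 + c2 * u2
    f1 <- stats::lm(u1 ~ w); f2 <- stats::lm(u2 ~ w)
    (sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)) /
      (stats::cor(u1, w) + stats::cor(u2, w))
  }
  set.seed(20)
  u1 <- stats::rnorm(20); u2 <- stats::rnorm(20)
  got <- ratio_cost(u1, u2, latent_weights(0, 0.3, 0.7))
  expect_equal(got, oracle(u1, u2, 0, 0.3, 0.7), tolerance = 1e-10)

  for (i in 1:5) {
    set.seed(100 + i)
    u1 <- stats::rnorm(15); u2 <- 0.4 * u1 + stats::rnorm(15)
    t <- stats::runif(1)
    expect_equal(ratio_cost(u1, u2, latent_weights(0, t, 1 - t)),
                 oracle(u1, u2, 0, t, 1 - t), tolerance = 1e-10)
  }
})

test_that("objective is flat in the offset c0", {
  set.seed(9)
  for (i in 1:10) {
    u1 <- stats::rnorm(25); u2 <- 0.5 * u1 + stats::rnorm(25)
    t <- stats::runif(1)
    base <- ratio_cost(u1, u2, latent_weights(0, t, 1 - t))
    for (c0 in c(-1, -0.4, 0.7, 1)) {
      expect_equal(ratio_cost(u1, u2, latent_weights(c0, t, 1 - t)), base,
                   tolerance = 1e-9)
    }
  }
})

test_that("solver dominates the dense grid and breaks flat ties at 0.5", {
  # identical inputs: objective 0 everywhere feasible -> equal weighting
  m <- optimize_latent(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(m$cost, 0, tolerance = 1e-12)
  expect_equal(m$weights$c1, 0.5)
  expect_equal(m$weights$c1 + m$weights$c2, 1, tolerance = 1e-12)

  # noiseless affine relation: flat zero objective, tie-break again
  u1 <- c(0.1, 0.5, 0.2, 0.9, 0.4)
  m2 <- optimize_latent(u1, 2 * u1 + 1)
  expect_equal(m2$cost, 0, tolerance = 1e-12)
  expect_equal(m2$weights$c1, 0.5)

  # grid dominance on seeded random instances
  for (i in 1:20) {
    set.seed(i)
    u1 <- stats::rnorm(30); u2 <- 0.6 * u1 + stats::rnorm(30, sd = 0.5)
    m <- optimize_latent(u1, u2)
    expect_lte(m$cost, grid_min_cost(u1, u2) + 1e-10)
  }
})

test_that("stored reconstruction coefficients reproduce the inner LS fits", {
  set.seed(31)
  u1 <- stats::rnorm(40); u2 <- 0.5 * u1 + stats::rnorm(40, sd = 0.3)
  m <- optimize_latent(u1, u2)
  W <- cbind(1, m$w_train)
  expect_equal(m$a1, unname(stats::lm.fit(W, u1)$coefficients), tolerance = 1e-10)
  expect_equal(m$a2, unname(stats::lm.fit(W, u2)$coefficients), tolerance = 1e-10)
})

test_that("latent regression matches the normal equations", {
  y <- c(0.1, 0.4, 0.3, 0.8, 0.6)
  expect_equal(fit_latent_regression(y, 3 + 2 * y), c(3, 2), tolerance = 1e-10)

  # projection of zero-mean noise orthogonal to the trend
  set.seed(8)
  y2 <- seq(0, 1, length.out = 50)
  w <- stats::rnorm(50)
  w <- stats::resid(stats::lm(w ~ y2)) + 0.3   # orthogonalized, mean shifted
  b <- fit_latent_regression(y2, w)
  expect_equal(b[2], 0, tolerance = 1e-10)
  expect_equal(b[1], mean(w), tolerance = 1e-10)

  # normal-equations oracle on a noisy instance
  set.seed(12)
  ys <- stats::runif(30); wv <- 0.2 + 1.5 * ys + stats::rnorm(30, sd = 0.1)
  A <- cbind(1, ys)
  expect_equal(fit_latent_regression(ys, wv),
               unname(drop(solve(crossprod(A), crossprod(A, wv)))),
               tolerance = 1e-10)

  expect_warning(fit_latent_regression(rep(0.5, 5), stats::rnorm(5)),
                 "constant")
})

test_that("LRP recovers the target response exactly in the noiseless regime", {
  g <- qgen(n_cells = 200, n_genes = 5, n_informative_genes = 5,
            expr_noise_sd = 0, auc_noise_sd = 0, latent_noise_sd = 0,
            latent_coeffs_target = c(0.5, 0.3),
            latent_coeffs_source = c(0.4, 0.5), seed = 2)
  y1 <- as.numeric(g$study$target_auc); y2 <- as.numeric(g$study$source_auc)
  tr <- 1:50; te <- 51:200
  out <- lrp_predict(y1[tr], y2[tr], y2[te])
  expect_lt(max(abs(out$pred - y1[te])), 1e-6)
})

test_that("LRP stays accurate under measurement noise", {
  g <- qgen(n_cells = 200, n_genes = 5, n_informative_genes = 5,
            expr_noise_sd = 0, auc_noise_sd = 0.02, latent_noise_sd = 0,
            latent_coeffs_target = c(0.5, 0.3),
            latent_coeffs_source = c(0.4, 0.5), seed = 3)
  y1 <- as.numeric(g$study$target_auc); y2 <- as.numeric(g$study$source_auc)
  tr <- 1:50; te <- 51:200
  out <- lrp_predict(y1[tr], y2[tr], y2[te])
  expect_gte(pearson(out$pred, y1[te]), 0.9)
})

test_that("LRP refuses prediction without matched source AUC", {
  y <- stats::runif(20, 0.2, 0.8)
  expect_error(lrp_predict(y[1:10], y[11:20], numeric(0)),
               class = "sensmap_applicability_error")
  y22 <- sensitivity_vector(c(0.3, NA, 0.5), c("a", "b", "c"), allow_na = TRUE)
  expect_error(lrp_predict(y[1:10], y[11:20], y22),
               class = "sensmap_applicability_error")
})

test_that("gene latent matrix concatenates per-gene optimizations", {
  g <- qgen(n_cells = 60, n_genes = 10, n_informative_genes = 3,
            expr_noise_sd = 0.4, seed = 11)
  X1 <- g$study$target_expr; X2 <- g$study$source_expr

  gl <- build_gene_latents(X1, X2)
  expect_identical(dim(gl$V), dim(unclass(X1)))
  # per-gene grid dominance
  for (k in seq_len(ncol(X1))) {
    expect_lte(gl$costs[k], grid_min_cost(X1[, k], X2[, k]) + 1e-10)
    lam <- gl$lambdas[, k]
    expect_equal(unname(lam["c1"] + lam["c2"]), 1, tolerance = 1e-12)
    expect_equal(gl$V[, k], lam["c1"] * X1[, k] + lam["c2"] * X2[, k],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }

  # identical matrices: every gene reaches zero cost
  gl0 <- build_gene_latents(X1, X1)
  expect_true(all(gl0$costs < 1e-10))

  # single-gene base case equals a direct optimization
  X1a <- expression_matrix(unclass(X1)[, 1, drop = FALSE])
  X2a <- expression_matrix(unclass(X2)[, 1, drop = FALSE])
  gl1 <- build_gene_latents(X1a, X2a)
  direct <- optimize_latent(X1[, 1], X2[, 1])
  expect_equal(unname(gl1$V[, 1]), unname(direct$w_train), tolerance = 1e-12)

  # degenerate constant column falls back, flagged, no abort
  X1c <- unclass(X1); X1c[, 2] <- 1
  expect_message(glc <- build_gene_latents(expression_matrix(X1c), X2),
                 "fallback")
  expect_true(glc$degenerate[2])
  expect_false(any(glc$degenerate[-2]))

  expect_error(build_gene_latents(X1, expression_matrix(unclass(X2)[1:10, ])),
               class = "sensmap_alignment_error")
})

test_that("LLP pipeline identity holds with an oracle latent regressor", {
  g <- qgen(n_cells = 80, n_genes = 6, n_informative_genes = 2, seed = 14)
  st <- g$study
  tr <- 1:30; te <- 31:80
  w2_true <- stats::rnorm(length(te))
  oracle <- function(X, y) function(newX) w2_true
  out <- llp_predict(st, tr, oracle)
  expect_equal(as.numeric(out$pred),
               out$model$a1[1] + out$model$a1[2] * w2_true, tolerance = 1e-12)

  expect_error(llp_predict(st, seq_len(80), oracle),
               class = "sensmap_validation_error")
})

test_that("LLP recovers an expression-determined response", {
  g <- qgen(n_cells = 200, n_genes = 4, n_informative_genes = 1,
            expr_noise_sd = 0, auc_noise_sd = 0, latent_noise_sd = 0,
            latent_coeffs_target = c(0.5, 0.12),
            latent_coeffs_source = c(0.45, 0.18), seed = 6)
  st <- g$study
  tr <- 1:50; te <- 51:200
  out <- llp_predict(st, tr)
  expect_gte(pearson(out$pred, as.numeric(st$target_auc)[te]), 0.95)
})

test_that("CLP averaging identities and applicability guard hold", {
  g <- qgen(n_cells = 80, n_genes = 6, n_informative_genes = 2, seed = 15)
  st <- g$study
  tr <- 1:30; te <- 31:80
  y1 <- as.numeric(st$target_auc); y2 <- as.numeric(st$source_auc)

  lrp <- lrp_predict(y1[tr], y2[tr], y2[te])
  # oracle LLP arm returning exactly the LRP latent: CLP must equal LRP
  clp <- clp_predict(st, tr, function(X, y) function(newX) lrp$w2)
  expect_equal(as.numeric(clp$pred), as.numeric(lrp$pred), tolerance = 1e-12)

  # anti-symmetric arms cancel: prediction collapses to the intercept
  clp2 <- clp_predict(st, tr, function(X, y) function(newX) -lrp$w2)
  expect_equal(as.numeric(clp2$pred),
               rep(clp2$model$a1[1], length(te)), tolerance = 1e-12)

  # missing matched source AUC at prediction cells
  y2na <- y2; y2na[te[1:5]] <- NA
  st_na <- st
  st_na$source_auc <- sensitivity_vector(y2na, names(st$source_auc), allow_na = TRUE)
  expect_error(clp_predict(st_na, tr, function(X, y) function(newX) lrp$w2),
               class = "sensmap_applicability_error")
})

test_that("CLP error is bounded by the worse latent arm on a pinned fixture", {
  g <- qgen(n_cells = 250, n_genes = 10, n_informative_genes = 3,
            expr_noise_sd = 0.3, auc_noise_sd = 0.03, seed = 18)
  st <- g$study
  tr <- 1:50; te <- 51:250
  y1 <- as.numeric(st$target_auc); y2 <- as.numeric(st$source_auc)
  truth <- y1[te]

  lrp <- lrp_predict(y1[tr], y2[tr], y2[te])
  llp <- llp_predict(st, tr)
  clp <- clp_predict(st, tr)
  expect_lte(nrmse(truth, clp$pred),
             max(nrmse(truth, lrp$pred), nrmse(truth, llp$pred)))
})
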