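# quiet generator wrapper: generator messages (squash fractions etc.) are
# exercised explicitly in the data-io tests, silenced elsewhere
qgen <- function(...) suppressMessages(generate_paired_study(synthetic_config(...)))

# deterministic linear-model regressor usable wherever a forest is overkill
linfit_regressor <- function(X, y) {
  cf <- stats::lm.fit(cbind(1, as.matrix(X)), as.numeric(y))$coefficients
  cf[is.na(cf)] <- 0
  function(newX) drop(cbind(1, as.matrix(newX)) %*% cf)
}

# tiny aligned study pair built by hand for io tests
tiny_study <- function(n = 6, p = 4, seed = 1) {
  set.seed(seed)
  cells <- paste0("C", seq_len(n)); genes <- paste0("g", seq_len(p))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(cells, genes))
  list(expr = expression_matrix(X),
       auc = sensitivity_vector(runif(n, 0.2, 0.8), cells, drug_id = "drugA"))
}

# grid minimum of the ratio cost computed through the definitional objective
grid_min_cost <- function(u1, u2, grid = 1001L) {
  ts <- seq(0, 1, length.out = grid)
  min(vapply(ts, function(t)
    ratio_cost(u1, u2, latent_weights(0, t, 1 - t)), numeric(1)))
}
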