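# deterministic fixtures shared across test files; everything is built in
# code so the suite needs no data files

# 4-cell, 1-variable world used for the 1-D optimizer oracle
oracle_world <- function() {
  list(
    bg = matrix(c(0, 1, 2, 3), ncol = 1, dimnames = list(NULL, "X")),
    pres = matrix(c(2, 3), ncol = 1, dimnames = list(NULL, "X"))
  )
}

# independent objective for a single linear feature on oracle_world();
# mirrors the model definition but is evaluated directly, not via the
# coordinate-descent path
oracle_objective <- function(lambda, rm = 1) {
  w <- oracle_world()
  f_b <- w$bg[, 1] / 3
  f_p <- w$pres[, 1] / 3
  m <- nrow(w$pres)
  beta <- rm * max(sd(f_p), 0.05) * 0.05 * (1 + 10 / sqrt(m))
  -mean(lambda * f_p) + log(sum(exp(lambda * f_b))) + beta * abs(lambda)
}

# small two-variable synthetic landscape with a known logistic truth
recovery_world <- function(seed, n_pres = 60) {
  spec <- data.frame(
    name = c("D1", "D2", "C1", "C2", "C3", "C4", "N1", "N2"),
    class = "climate", smoothing = 3
  )
  r <- diag(8)
  r[1, 3] <- r[3, 1] <- 0.92  # C1, C2 shadow D1
  r[1, 4] <- r[4, 1] <- 0.92
  r[2, 5] <- r[5, 2] <- 0.92  # C3, C4 shadow D2
  r[2, 6] <- r[6, 2] <- 0.92
  r[3, 4] <- r[4, 3] <- 0.92 * 0.92
  r[5, 6] <- r[6, 5] <- 0.92 * 0.92
  st <- gen_stack(seed, layer_spec = spec, target_corr = r)
  # a rare, sharply defined niche (~8% of cells highly suitable): the
  # Bayes-optimal AUC of this truth is ~0.92, the regime the workflow is
  # designed to operate in
  truth <- gen_true_suitability(st, c(D1 = 3, D2 = -3), intercept = -6)
  occ <- sample_occurrences(truth, n_pres, seed = seed + 1000)
  list(stack = st, truth = truth, occ = occ,
       pres = extract_matrix(occ, st), bg = stack_matrix(st))
}

# tiny deterministic suitability raster for classification tests
suit_grid <- function(values = seq(0, 1, length.out = 25), nrow = 5) {
  raster_grid(matrix(values, nrow = nrow, byrow = TRUE))
}

expect_sums_to <- function(x, total, tol = 0.01) {
  expect_lt(abs(sum(x) - total), tol)
}
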