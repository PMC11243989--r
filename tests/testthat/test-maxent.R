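test_that("feature counts follow the class definitions", {
  pres <- matrix(runif(6), 3, 2, dimnames = list(NULL, c("A", "B")))
  bg <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("A", "B")))
  fd_l <- build_features(pres[, 1, drop = FALSE], bg[, 1, drop = FALSE],
                         feature_config("L"))
  expect_equal(ncol(fd_l$bg), 1)
  pres3 <- cbind(pres, C = runif(3)); bg3 <- cbind(bg, C = runif(10))
  fd <- build_features(pres3, bg3, feature_config("LQP"))
  expect_equal(ncol(fd$bg), 3 + 3 + 3)
  fd_h <- build_features(pres3, bg3, feature_config("H", hinge_knots = 5))
  expect_equal(ncol(fd_h$bg), 3 * 5 * 2)
  fd_t <- build_features(pres3, bg3, feature_config("T", threshold_knots = 4))
  expect_equal(ncol(fd_t$bg), 3 * 4)
})

test_that("linear features are background min/max scaled to [0, 1]", {
  bg <- matrix(c(2, 4, 6, 10), ncol = 1, dimnames = list(NULL, "X"))
  pres <- matrix(c(10, 2), ncol = 1, dimnames = list(NULL, "X"))
  fd <- build_features(pres, bg, feature_config("L"))
  expect_equal(as.numeric(fd$pres), c(1, 0))
  expect_equal(range(fd$bg), c(0, 1))
})

test_that("zero-variance variables are dropped with a warning", {
  bg <- cbind(X = runif(10), Z = rep(3, 10))
  pres <- cbind(X = runif(4), Z = rep(3, 4))
  expect_warning(fd <- build_features(pres, bg, feature_config("L")),
                 "zero-variance")
  expect_equal(colnames(fd$bg), "L:X")
})

test_that("the fit matches an independent 1-D oracle", {
  w <- oracle_world()
  fd <- build_features(w$pres, w$bg, feature_config("L", rm = 1))
  fit <- fit_maxent(fd, rm = 1)
  opt <- optimize(oracle_objective, c(-50, 50), tol = 1e-12)
  expect_lt(abs(unname(fit$lambda) - opt$minimum), 1e-4)
  expect_lt(oracle_objective(unname(fit$lambda)) - opt$objective, 1e-8)
  # training gain at the fitted optimum equals the direct formula
  f_p <- w$pres[, 1] / 3; f_b <- w$bg[, 1] / 3
  gain_direct <- mean(unname(fit$lambda) * f_p) -
    log(sum(exp(unname(fit$lambda) * f_b))) + log(4)
  expect_equal(training_gain(fit), gain_direct, tolerance = 1e-10)
})

test_that("two-feature fits reach the exhaustive grid oracle", {
  # <= 2 features, <= 10 background cells: grid search over lambda pairs
  set.seed(8)
  bg <- cbind(A = runif(8), B = runif(8))
  pres <- bg[c(6, 7, 8, 8), ]
  fd <- build_features(pres[, "A", drop = FALSE], bg[, "A", drop = FALSE],
                       feature_config("LQ"))
  fit <- fit_maxent(fd, rm = 1)
  Fp <- fd$pres; Fb <- fd$bg
  m <- nrow(Fp)
  s <- pmax(apply(Fp, 2, sd), 0.05)
  beta <- 1 * s * 0.05 * (1 + 10 / sqrt(m))
  Jfun <- function(l) {
    -mean(Fp %*% l) + log(sum(exp(Fb %*% l))) + sum(beta * abs(l))
  }
  grid <- seq(-8, 8, by = 0.02)
  best <- Inf
  for (l1 in grid) {
    obj <- vapply(grid, function(l2) Jfun(c(l1, l2)), 0)
    best <- min(best, min(obj))
  }
  expect_lt(Jfun(as.numeric(fit$lambda)) - best, 1e-3)
})

test_that("huge regularization collapses to the uniform model", {
  w <- oracle_world()
  fd <- build_features(w$pres, w$bg, feature_config("LQ"))
  fit <- fit_maxent(fd, rm = 1e6)
  expect_true(all(fit$lambda == 0))
  expect_equal(training_gain(fit), 0)
  raw <- predict_raw(fit)
  expect_equal(raw, rep(1 / 4, 4))
  cl <- predict_cloglog(fit, w$bg)
  expect_equal(cl, rep(1 - exp(-1), 4), tolerance = 1e-12)
})

test_that("presences covering the background give a near-null model", {
  set.seed(2)
  bg <- cbind(A = runif(30), B = runif(30))
  fd <- build_features(bg, bg, feature_config("LQ"))
  fit <- fit_maxent(fd)
  expect_lt(training_gain(fit), 0.02)
})

test_that("raw predictions normalize and cloglog preserves ranking", {
  set.seed(4)
  bg <- cbind(A = runif(50), B = runif(50))
  pres <- bg[order(bg[, "A"])[41:50], ]
  fd <- build_features(pres, bg, feature_config("LQH", hinge_knots = 5))
  fit <- fit_maxent(fd)
  raw <- predict_raw(fit)
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  expect_true(all(raw >= 0))
  cl <- predict_cloglog(fit, bg)
  expect_true(all(cl >= 0 & cl <= 1))
  expect_equal(order(raw), order(cl))
  # doubling every weight preserves the raw ordering (monotone transform)
  fit2 <- fit
  fit2$lambda <- fit$lambda * 2
  expect_equal(order(predict_raw(fit2)), order(raw))
})

test_that("cloglog maps propagate nodata and stay in [0, 1]", {
  spec <- data.frame(name = c("A", "B"), class = "climate", smoothing = 2)
  st <- gen_stack(6, layer_spec = spec)
  truth <- gen_true_suitability(st, c(A = 2), intercept = -1)
  occ <- sample_occurrences(truth, 30, seed = 3)
  fd <- build_features(extract_matrix(occ, st), stack_matrix(st),
                       feature_config("LQ"))
  fit <- fit_maxent(fd)
  suit <- predict_cloglog(fit, st)
  expect_identical(is.na(suit$values), is.na(st$layers$A$values))
  expect_true(all(na.omit(as.numeric(suit$values)) >= 0))
  expect_true(all(na.omit(as.numeric(suit$values)) <= 1))
})

test_that("stronger regularization shrinks the solution monotonically", {
  set.seed(9)
  bg <- cbind(A = runif(60), B = runif(60), C = runif(60))
  pres <- bg[order(bg[, "A"] + 0.5 * bg[, "B"])[51:60], ]
  fd <- build_features(pres, bg, feature_config("LQP"))
  fits <- lapply(c(0.5, 1, 2, 4, 8), function(rm) fit_maxent(fd, rm = rm))
  # the L1 norm of the optimum is nonincreasing in the penalty strength
  # (the active-set COUNT can wobble along an L1 path; the norm cannot)
  l1 <- vapply(fits, function(f) sum(abs(f$lambda)), 0)
  expect_true(all(diff(l1) <= 1e-8))
  ks <- vapply(fits, function(f) sum(f$lambda != 0), 0L)
  expect_lte(ks[length(ks)], ks[1])
})

test_that("degenerate all-identical presences return a finite optimum", {
  bg <- matrix(c(0, 1, 2, 3), ncol = 1, dimnames = list(NULL, "X"))
  pres <- matrix(c(3, 3, 3), ncol = 1, dimnames = list(NULL, "X"))
  fd <- build_features(pres, bg, feature_config("L"))
  fit <- fit_maxent(fd)
  expect_true(is.finite(fit$lambda))
  expect_true(fit$convergence$converged)
})

test_that("model serialization round-trips predictions", {
  set.seed(10)
  bg <- cbind(A = runif(40), B = runif(40))
  pres <- bg[order(bg[, "B"])[31:40], ]
  fd <- build_features(pres, bg, feature_config("LQH", hinge_knots = 4))
  fit <- fit_maxent(fd)
  f <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(fit, f)
  back <- read_maxent_model(f)
  expect_equal(predict_cloglog(back, bg), predict_cloglog(fit, bg),
               tolerance = 1e-12)
})
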