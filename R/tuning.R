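#' Rank-based AUC
#'
#' Mann--Whitney statistic: the probability that a randomly chosen presence
#' outscores a randomly chosen background point, ties counted one half.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  stopifnot(m >= 1, n >= 1)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' 10 percent training omission rate
#'
#' The threshold is the 10th percentile (linear-interpolation quantile) of
#' the training presence scores; the rate is the fraction of test presences
#' strictly below it.
#'
#' @param train_scores,test_scores presence score vectors.
#' @return omission rate in \[0, 1\].
#' @export
or10 <- function(train_scores, test_scores) {
  thr <- as.numeric(stats::quantile(train_scores, 0.10, type = 7))
  mean(test_scores < thr)
}

#' Verbal grade of a mean AUC
#'
#' Half-open bins: fail or inadequate \[0.5, 0.6), poor \[0.6, 0.7),
#' reasonable or fair \[0.7, 0.8), good \[0.8, 0.9), perfect or excellent
#' \[0.9, 1.0\].
#'
#' @param auc_mean mean AUC (at least 0.5).
#' @return character label.
#' @export
grade_auc <- function(auc_mean) {
  stopifnot(auc_mean >= 0.5 - 1e-12, auc_mean <= 1 + 1e-12)
  if (auc_mean < 0.6) "fail or inadequate"
  else if (auc_mean < 0.7) "poor"
  else if (auc_mean < 0.8) "reasonable or fair"
  else if (auc_mean < 0.9) "good"
  else "perfect or excellent"
}

#' Sample-size-corrected AIC of a fitted model
#'
#' Raw predictions are standardized to sum to one over the study cells;
#' `lnL` is the summed log standardized raw value at the occurrence points;
#' `k` counts nonzero feature weights;
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`. Undefined (`NA`) when
#' `n <= k + 1`.
#'
#' @param model a fitted `maxent_model`.
#' @param occ_raw raw-variable matrix of all occurrence points.
#' @return list with `aicc`, `lnL`, `k`, `n`.
#' @export
aicc <- function(model, occ_raw) {
  n <- nrow(occ_raw)
  raw_bg <- predict_raw(model)
  raw_occ <- predict_raw(model, occ_raw)
  std <- raw_occ / sum(raw_bg)
  lnL <- sum(log(pmax(std, 1e-300)))
  k <- sum(model$lambda != 0)
  val <- if (n <= k + 1) NA_real_ else 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
  list(aicc = val, lnL = lnL, k = k, n = n)
}

#' Bootstrap replicate evaluation of one (RM, FC) combination
#'
#' Per replicate, the training set is a bootstrap resample (with
#' replacement) of size `ceiling(train_frac * n)` of the presence points
#' and the test set the points never drawn; the model is refit on the
#' training presences against the full background, and training/test AUC,
#' their difference, and the 10 percent omission rate are recorded.
#' Replicates whose out-of-bag test set is empty are redrawn.
#'
#' @param presence raw-variable matrix of presence points.
#' @param background raw-variable matrix of background cells.
#' @param config a [feature_config] (carries FC and RM).
#' @param n_rep number of replicates.
#' @param train_frac training fraction.
#' @param seed RNG seed.
#' @param max_iter,tol optimizer settings.
#' @return list of class `evaluation_summary`: per-replicate table
#'   `replicates` (auc_train, auc_test, auc_diff, or10), means and sds,
#'   the AUC grade, per-replicate test scores and the shared background
#'   scores (cloglog scale) for downstream thresholding.
#' @export
evaluate_replicates <- function(presence, background,
                                config = feature_config(),
                                n_rep = 10, train_frac = 0.75, seed = 1,
                                max_iter = 500, tol = 1e-5) {
  n <- nrow(presence)
  stopifnot(n >= 4)
  rows <- vector("list", n_rep)
  test_scores <- vector("list", n_rep)
  bg_scores <- vector("list", n_rep)
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      for (attempt in 1:100) {
        tr <- sample(n, ceiling(train_frac * n), replace = TRUE)
        te <- setdiff(seq_len(n), unique(tr))
        if (length(te) >= 1) break
      }
      if (length(te) == 0) stop("bootstrap produced no out-of-bag test points")
      fd <- build_features(presence[tr, , drop = FALSE], background, config)
      fit <- suppressWarnings(fit_maxent(fd, max_iter = max_iter, tol = tol))
      s_tr <- predict_cloglog(fit, presence[tr, , drop = FALSE])
      s_te <- predict_cloglog(fit, presence[te, , drop = FALSE])
      s_bg <- predict_cloglog(fit, background)
      rows[[r]] <- data.frame(
        replicate = r,
        auc_train = auc(s_tr, s_bg),
        auc_test = auc(s_te, s_bg),
        or10 = or10(s_tr, s_te)
      )
      test_scores[[r]] <- s_te
      bg_scores[[r]] <- s_bg
    }
  })
  tab <- do.call(rbind, rows)
  tab$auc_diff <- tab$auc_train - tab$auc_test
  structure(
    list(replicates = tab,
         auc_train_mean = mean(tab$auc_train),
         auc_train_sd = stats::sd(tab$auc_train),
         auc_diff_mean = mean(tab$auc_diff),
         auc_diff_sd = stats::sd(tab$auc_diff),
         or10_mean = mean(tab$or10),
         grade = grade_auc(max(0.5, mean(tab$auc_train))),
         test_scores = test_scores,
         background_scores = bg_scores),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_summary> AUC_train %.3f +/- %.3f (%s), ",
                     "AUC_DIFF %.3f +/- %.3f, OR_10 %.3f, %d replicates\n"),
              x$auc_train_mean, x$auc_train_sd, x$grade,
              x$auc_diff_mean, x$auc_diff_sd, x$or10_mean,
              nrow(x$replicates)))
  invisible(x)
}

#' Tune the regularization multiplier and feature classes
#'
#' Fits one model per (RM, FC) combination on all presence points, scores
#' it with [aicc()], and evaluates each combination with
#' [evaluate_replicates()]. The default grids (RM 0.5--4 by 0.5; FC in
#' L, LQ, H, LQH, LQHP, LQHPT) give 48 combinations.
#'
#' @param presence,background raw-variable matrices.
#' @param rm_values distinct regularization multipliers.
#' @param fc_sets feature-class strings.
#' @param seed RNG seed (fans out per combination).
#' @param n_rep bootstrap replicates per combination for the AUC metrics.
#' @param hinge_knots,threshold_knots knots per variable.
#' @param max_iter,tol optimizer settings.
#' @return data.frame of class `tuning_table`: one row per combination with
#'   fc, rm, k, lnL, aicc, delta_aicc, auc_train, auc_test, auc_diff, or10.
#' @export
tune_grid <- function(presence, background,
                      rm_values = seq(0.5, 4, by = 0.5),
                      fc_sets = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"),
                      seed = 1, n_rep = 3,
                      hinge_knots = 15, threshold_knots = 15,
                      max_iter = 500, tol = 1e-5) {
  if (anyDuplicated(rm_values)) stop("duplicate rm values")
  if (anyDuplicated(fc_sets)) stop("duplicate fc sets")
  combos <- expand.grid(rm = rm_values, fc = fc_sets,
                        stringsAsFactors = FALSE)
  # keep the documented ordering: fc-major, rm within fc
  combos <- combos[order(match(combos$fc, fc_sets), combos$rm), ]
  seeds <- derive_seeds(seed, nrow(combos))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- feature_config(combos$fc[i], combos$rm[i],
                          hinge_knots, threshold_knots)
    fd <- build_features(presence, background, cfg)
    fit <- suppressWarnings(fit_maxent(fd, max_iter = max_iter, tol = tol))
    ic <- aicc(fit, presence)
    ev <- evaluate_replicates(presence, background, cfg, n_rep = n_rep,
                              seed = seeds[i], max_iter = max_iter,
                              tol = tol)
    data.frame(fc = combos$fc[i], rm = combos$rm[i],
               k = ic$k, lnL = ic$lnL, aicc = ic$aicc,
               auc_train = ev$auc_train_mean, auc_test = mean(ev$replicates$auc_test),
               auc_diff = ev$auc_diff_mean, or10 = ev$or10_mean)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$aicc)
  tab$delta_aicc <- NA_real_
  if (any(ok)) tab$delta_aicc[ok] <- tab$aicc[ok] - min(tab$aicc[ok])
  class(tab) <- c("tuning_table", class(tab))
  tab
}

#' Select the best (FC, RM) combination from a tuning table
#'
#' The row with delta AICc = 0; ties broken by smaller k, then larger rm,
#' then feature-class order of appearance. Rows with undefined AICc
#' (n <= k + 1) are excluded from the ranking.
#'
#' @param table a `tuning_table` from [tune_grid()].
#' @return list with `fc`, `rm` and the selected `row`.
#' @export
select_best <- function(table) {
  ok <- which(!is.na(table$aicc))
  if (length(ok) == 0) stop("no combination has a defined AICc")
  cand <- table[ok, ]
  cand <- cand[cand$aicc <= min(cand$aicc) + 1e-9, , drop = FALSE]
  cand <- cand[order(cand$k, -cand$rm), , drop = FALSE]
  best <- cand[1, ]
  list(fc = best$fc, rm = best$rm, row = best)
}
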