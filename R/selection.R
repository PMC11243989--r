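#' Preliminary screening and ranking of environmental variables
#'
#' Fits `n_runs` replicate models with the default settings (FC = LQHPT,
#' RM = 1) -- the first on the full presence set, the rest on bootstrap
#' resamples of it -- averages permutation importance and percent
#' contribution per variable across the replicates, removes variables
#' whose mean contribution is below `contribution_cut` percent, and ranks
#' the survivors by descending mean permutation importance (ties broken
#' alphabetically). Replicate refits matter with collinear predictors: a
#' single L1 fit splits weight near-arbitrarily within a correlated
#' group, and averaging over resamples lets the variable that genuinely
#' carries the signal come out ahead.
#'
#' @param matrix an [extract_matrix()] result or raw-variable matrix of
#'   presence points.
#' @param background raw-variable matrix of background cells.
#' @param n_runs number of replicate screening runs.
#' @param seed RNG seed (fans out per run).
#' @param contribution_cut removal threshold on mean percent contribution.
#' @param config screening [feature_config].
#' @param max_iter,tol optimizer settings.
#' @return data.frame of class `variable_ranking` with columns `variable`,
#'   `perm_importance`, `contribution`, `rank` and attribute
#'   `dropped_by_contribution`.
#' @export
screen_and_rank <- function(matrix, background, n_runs = 3, seed = 1,
                            contribution_cut = 1,
                            config = feature_config("LQHPT", 1),
                            max_iter = 500, tol = 1e-5) {
  pres <- as.matrix(matrix)
  stopifnot(ncol(pres) >= 2)
  vars <- colnames(pres)
  seeds <- derive_seeds(seed, 2 * n_runs)
  # replicate runs refit on bootstrap resamples of the presences (the
  # replication mechanism of the reference workflow); averaging the
  # importance measures over replicates stabilizes the near-arbitrary
  # choice an L1 fit makes among strongly collinear variables
  m <- nrow(pres)
  imp_sum <- stats::setNames(numeric(length(vars)), vars)
  con_sum <- stats::setNames(numeric(length(vars)), vars)
  fit_vars <- vars
  for (r in seq_len(n_runs)) {
    idx <- if (r == 1) seq_len(m) else
      with_seed(seeds[r], sample(m, m, replace = TRUE))
    fd <- build_features(pres[idx, , drop = FALSE], background, config)
    fit <- suppressWarnings(fit_maxent(fd, max_iter = max_iter, tol = tol))
    fit_vars <- intersect(fit_vars, fit$variables)
    imp <- suppressWarnings(
      permutation_importance(fit, seed = seeds[n_runs + r]))
    con <- percent_contribution(fit)
    imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
    con_sum[names(con)] <- con_sum[names(con)] + con
  }
  imp <- imp_sum / n_runs
  contrib <- con_sum / n_runs
  kept_vars <- intersect(vars, fit_vars)
  contrib <- contrib[kept_vars]
  imp <- imp[kept_vars]
  low <- kept_vars[contrib < contribution_cut]
  survivors <- setdiff(kept_vars, low)
  if (length(survivors) == 0) {
    stop("degenerate screening: every variable is below the contribution cut")
  }
  out <- data.frame(variable = survivors,
                    perm_importance = unname(imp[survivors]),
                    contribution = unname(contrib[survivors]),
                    row.names = NULL)
  out <- out[order(-out$perm_importance, out$variable), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "dropped_by_contribution") <- low
  class(out) <- c("variable_ranking", class(out))
  out
}

#' Pearson pair filtering of collinear variables
#'
#' Pearson r is computed between the supplied value columns (background
#' cells or the occurrence matrix, see [run_variable_selection()]); pairs
#' with `|r| >= r_thresh` are processed in descending `|r|` (ties
#' alphabetical), and in each pair whose members both still survive the
#' lower-ranked variable is dropped, keeping the one more important to
#' the model.
#'
#' @param matrix raw-variable matrix (rows are cells or points).
#' @param ranking a `variable_ranking` covering the candidate variables.
#' @param r_thresh absolute correlation threshold.
#' @return list with `retained` (character) and `report` (data.frame of
#'   kept, dropped, r).
#' @export
pearson_filter <- function(matrix, ranking, r_thresh = 0.8) {
  vars <- ranking$variable
  missing_v <- setdiff(vars, colnames(matrix))
  if (length(missing_v) > 0) {
    stop("matrix lacks ranked variable(s): ", paste(missing_v, collapse = ", "))
  }
  x <- as.matrix(matrix)[, vars, drop = FALSE]
  cm <- stats::cor(x)
  pairs <- which(upper.tri(cm) & abs(cm) >= r_thresh, arr.ind = TRUE)
  report <- data.frame(kept = character(0), dropped = character(0),
                       r = numeric(0))
  if (nrow(pairs) > 0) {
    pr <- data.frame(a = vars[pairs[, 1]], b = vars[pairs[, 2]],
                     r = cm[pairs])
    # alphabetical pair identity for reproducible tie order
    swap <- pr$a > pr$b
    tmp <- pr$a[swap]; pr$a[swap] <- pr$b[swap]; pr$b[swap] <- tmp
    pr <- pr[order(-abs(pr$r), pr$a, pr$b), ]
    alive <- stats::setNames(rep(TRUE, length(vars)), vars)
    rk <- stats::setNames(ranking$rank, ranking$variable)
    for (i in seq_len(nrow(pr))) {
      a <- pr$a[i]; b <- pr$b[i]
      if (!alive[a] || !alive[b]) next
      drop_v <- if (rk[a] > rk[b]) a else b
      keep_v <- if (drop_v == a) b else a
      alive[drop_v] <- FALSE
      report <- rbind(report, data.frame(kept = keep_v, dropped = drop_v,
                                         r = pr$r[i]))
    }
    vars <- vars[alive[vars]]
  }
  list(retained = vars, report = report)
}

#' Variance inflation factors of a variable set
#'
#' `VIF_j = 1 / (1 - R^2_j)` with `R^2_j` from the ordinary least squares
#' regression of column j on all other columns (intercept included).
#'
#' @param x numeric matrix (rows x variables), at least 2 columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    1 / max(1 - r2, 1e-12)
  }, 0) |> stats::setNames(colnames(x))
}

#' Iterative VIF elimination
#'
#' While the largest VIF exceeds `vif_thresh`, the variable with the
#' largest VIF is removed and all VIFs recomputed. With fewer than two
#' variables nothing is done (VIF undefined).
#'
#' @param matrix raw-variable matrix restricted to the surviving variables.
#' @param vif_thresh removal threshold.
#' @return list with `retained` and `report` (variable, vif at removal).
#' @export
vif_filter <- function(matrix, vif_thresh = 5) {
  x <- as.matrix(matrix)
  report <- data.frame(variable = character(0), vif = numeric(0))
  while (ncol(x) >= 2) {
    v <- vif(x)
    if (max(v) <= vif_thresh) break
    worst <- names(v)[order(-v, names(v))][1]
    report <- rbind(report,
                    data.frame(variable = worst, vif = unname(v[worst])))
    x <- x[, setdiff(colnames(x), worst), drop = FALSE]
  }
  list(retained = colnames(x), report = report)
}

#' Final top-k variable selection
#'
#' The `k` highest-ranked survivors, ordered by descending permutation
#' importance; if fewer than `k` survive, all are returned with a warning.
#'
#' @param ranking a `variable_ranking`.
#' @param survivors character vector of variables that passed both
#'   collinearity filters.
#' @param k maximum number of final predictors.
#' @return character vector of final variables.
#' @export
select_final <- function(ranking, survivors, k = 5) {
  rk <- ranking[ranking$variable %in% survivors, ]
  rk <- rk[order(rk$rank), ]
  if (nrow(rk) < k) {
    warning(sprintf("only %d variable(s) survive the filters (requested %d)",
                    nrow(rk), k))
    return(rk$variable)
  }
  rk$variable[seq_len(k)]
}

#' Run the full five-step variable-selection workflow
#'
#' Screening and ranking, sub-1-percent contribution removal, Pearson pair
#' filtering, iterative VIF elimination, and top-k selection, with a full
#' decision-path report.
#'
#' @param matrix raw-variable matrix of presence points.
#' @param background raw-variable matrix of background cells.
#' @param n_runs screening replicate runs.
#' @param seed RNG seed.
#' @param contribution_cut,r_thresh,vif_thresh,k workflow thresholds.
#' @param cor_data which values the Pearson and VIF collinearity filters
#'   are computed on: `"background"` (default; all study-area cells) or
#'   `"presence"` (the occurrence data matrix). Collinearity is a property
#'   of the environmental layers over the landscape; presence-point
#'   correlations are attenuated by range restriction and pick up spurious
#'   structure at small sample sizes (see the package vignette).
#' @param max_iter,tol optimizer settings.
#' @return list of class `selection_report`: `final_set`, `ranking`,
#'   `dropped_by_contribution`, `dropped_by_pearson`, `dropped_by_vif`.
#' @export
run_variable_selection <- function(matrix, background, n_runs = 3, seed = 1,
                                   contribution_cut = 1, r_thresh = 0.8,
                                   vif_thresh = 5, k = 5,
                                   cor_data = c("background", "presence"),
                                   max_iter = 500, tol = 1e-5) {
  cor_data <- match.arg(cor_data)
  ranking <- screen_and_rank(matrix, background, n_runs = n_runs,
                             seed = seed, contribution_cut = contribution_cut,
                             max_iter = max_iter, tol = tol)
  cor_m <- if (cor_data == "background") as.matrix(background)
           else as.matrix(matrix)
  pf <- pearson_filter(cor_m, ranking, r_thresh = r_thresh)
  vf <- vif_filter(cor_m[, pf$retained, drop = FALSE],
                   vif_thresh = vif_thresh)
  final <- select_final(ranking, vf$retained, k = k)
  structure(
    list(final_set = final,
         ranking = ranking,
         dropped_by_contribution = attr(ranking, "dropped_by_contribution"),
         dropped_by_pearson = pf$report,
         dropped_by_vif = vf$report),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat("  final set:", paste(x$final_set, collapse = ", "), "\n")
  cat("  dropped (<1% contribution):",
      paste(x$dropped_by_contribution, collapse = ", "), "\n")
  cat("  dropped (Pearson):",
      paste(x$dropped_by_pearson$dropped, collapse = ", "), "\n")
  cat("  dropped (VIF):",
      paste(x$dropped_by_vif$variable, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection report to CSV files
#'
#' @param report a `selection_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_selection_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$ranking, file.path(dir, "ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(report$dropped_by_pearson,
                   file.path(dir, "dropped_pearson.csv"), row.names = FALSE)
  utils::write.csv(report$dropped_by_vif,
                   file.path(dir, "dropped_vif.csv"), row.names = FALSE)
  writeLines(c(
    paste("final set:", paste(report$final_set, collapse = ",")),
    paste("dropped by contribution:",
          paste(report$dropped_by_contribution, collapse = ","))
  ), file.path(dir, "selection_log.txt"))
  invisible(dir)
}
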