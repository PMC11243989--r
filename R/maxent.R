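#' Fit a presence-background maximum-entropy model
#'
#' Minimizes the L1-regularized objective
#' \deqn{J(\lambda) = -\frac{1}{m}\sum_{presence} \lambda' f(x)
#'   + \ln Z(\lambda) + \sum_j \beta_j |\lambda_j|}
#' where \eqn{Z(\lambda) = \sum_{background} e^{\lambda' f(x)}} is the
#' partition function over background cells, by cyclic coordinate descent
#' with an analytic soft-threshold step on a local quadratic approximation
#' (step-halved whenever the exact objective would not decrease). The
#' per-feature penalty is \eqn{\beta_j = rm \cdot s_j \cdot c(class, m)}
#' with \eqn{s_j} the presence-sample standard deviation of feature j
#' (floored at 0.05 so degenerate presence sets remain penalized) and
#' class constants 0.05(1 + 10/sqrt(m)) for linear/quadratic/product, 0.5
#' for hinge, 1.0 for threshold.
#'
#' @param features a [feature_design] from [build_features()].
#' @param rm regularization multiplier; defaults to the one in the design's
#'   config.
#' @param max_iter maximum number of coordinate-descent sweeps.
#' @param tol convergence threshold on the largest coefficient change in a
#'   sweep.
#' @return An object of class `maxent_model`: feature weights `lambda`,
#'   feature `defs` and `scaling`, `lnZ`, entropy `H` of the fitted
#'   distribution over the background, penalty weights `beta`, per-variable
#'   percent-contribution tallies, and a convergence record.
#' @export
fit_maxent <- function(features, rm = NULL, max_iter = 500, tol = 1e-5) {
  stopifnot(inherits(features, "feature_design"))
  rm_ <- rm %||% features$config$rm
  Fp <- features$pres
  Fb <- features$bg
  m <- nrow(Fp); nb <- nrow(Fb)
  if (m < 2 || nb < 2) stop("need at least 2 presence and 2 background rows")
  J <- ncol(Fb)
  pbar <- colMeans(Fp)
  s <- pmax(apply(Fp, 2, stats::sd), 0.05)
  cls <- features$defs$class
  cc <- ifelse(cls %in% c("L", "Q", "P"), 0.05 * (1 + 10 / sqrt(m)),
        ifelse(cls %in% c("HF", "HR"), 0.5, 1.0))
  beta <- rm_ * s * cc

  lambda <- numeric(J)
  eta_b <- numeric(nb)
  eta_p <- numeric(m)
  lse <- function(eta) { mx <- max(eta); mx + log(sum(exp(eta - mx))) }
  lnZ <- lse(eta_b)
  q <- exp(eta_b - lnZ)
  jdata <- -mean(eta_p) + lnZ
  jpen <- 0
  tally <- stats::setNames(numeric(length(unique(
    c(features$defs$var1, stats::na.omit(features$defs$var2))))),
    unique(c(features$defs$var1, stats::na.omit(features$defs$var2))))

  update_one <- function(j) {
    fj_b <- Fb[, j]
    Ef <- sum(q * fj_b)
    h <- max(sum(q * fj_b^2) - Ef^2, 1e-8)
    g <- Ef - pbar[j]
    z <- lambda[j] - g / h
    lam_new <- sign(z) * max(abs(z) - beta[j] / h, 0)
    delta <- lam_new - lambda[j]
    if (abs(delta) < 1e-12) return(0)
    for (halve in 0:20) {
      cand <- lambda[j] + delta
      eta_b2 <- eta_b + delta * fj_b
      lnZ2 <- lse(eta_b2)
      jdata2 <- -(mean(eta_p) + delta * pbar[j]) + lnZ2
      jpen2 <- jpen + beta[j] * (abs(cand) - abs(lambda[j]))
      if (jdata2 + jpen2 <= jdata + jpen + 1e-12) {
        # accept; credit the data-fit improvement to the feature's variable
        v1 <- features$defs$var1[j]; v2 <- features$defs$var2[j]
        dd <- abs(jdata2 - jdata)
        if (is.na(v2)) tally[v1] <<- tally[v1] + dd
        else { tally[v1] <<- tally[v1] + dd / 2; tally[v2] <<- tally[v2] + dd / 2 }
        lambda[j] <<- cand
        eta_b <<- eta_b2
        eta_p <<- eta_p + delta * Fp[, j]
        lnZ <<- lnZ2
        q <<- exp(eta_b - lnZ)
        jdata <<- jdata2
        jpen <<- jpen2
        return(delta)
      }
      delta <- delta / 2
      if (abs(delta) < 1e-12) break
    }
    0
  }

  sweeps <- 0
  final_change <- Inf
  repeat {
    sweeps <- sweeps + 1
    maxd <- 0
    for (j in seq_len(J)) maxd <- max(maxd, abs(update_one(j)))
    final_change <- maxd
    if (maxd < tol || sweeps >= max_iter) break
    # refine over the current active set before the next full sweep
    for (inner in 1:25) {
      act <- which(lambda != 0)
      if (length(act) == 0) break
      maxd_a <- 0
      for (j in act) maxd_a <- max(maxd_a, abs(update_one(j)))
      if (maxd_a < tol) break
    }
  }

  H <- -sum(q * log(pmax(q, 1e-300)))
  structure(
    list(lambda = stats::setNames(lambda, features$defs$feature),
         defs = features$defs, scaling = features$scaling,
         config = features$config, rm = rm_,
         lnZ = lnZ, H = H, beta = beta,
         m = m, n_bg = nb,
         variables = features$scaling$var,
         pres_raw = features$pres_raw, bg_raw = features$bg_raw,
         eta_pres = eta_p, eta_bg = eta_b,
         contribution_tally = tally,
         convergence = list(sweeps = sweeps, final_change = final_change,
                            converged = final_change < tol)),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> FC=%s RM=%g: %d/%d nonzero features, ",
                     "%d presences, %d background cells, gain %.4f\n"),
              x$config$fc, x$rm, sum(x$lambda != 0), length(x$lambda),
              x$m, x$n_bg, training_gain(x)))
  invisible(x)
}

# linear predictor for raw-variable rows under a fitted model
model_eta <- function(model, raw) {
  raw <- as.matrix(raw)[, model$variables, drop = FALSE]
  nz <- which(model$lambda != 0)
  if (length(nz) == 0) return(numeric(nrow(raw)))
  f <- feature_rows(model$defs[nz, , drop = FALSE], model$scaling, raw)
  as.numeric(f %*% model$lambda[nz])
}

#' Raw (Gibbs) prediction
#'
#' `raw(x) = exp(lambda . f(x)) / Z`, with Z the training-background
#' partition function; over the training background these sum to 1.
#'
#' @param model a fitted `maxent_model`.
#' @param newdata raw-variable matrix (rows x variables), a
#'   [scenario_stack], or `NULL` for the training background.
#' @return numeric vector of nonnegative raw values.
#' @export
predict_raw <- function(model, newdata = NULL) {
  raw <- raw_rows(model, newdata)
  exp(model_eta(model, raw) - model$lnZ)
}

raw_rows <- function(model, newdata) {
  if (is.null(newdata)) return(model$bg_raw)
  if (inherits(newdata, "scenario_stack")) {
    sm <- stack_matrix(newdata)
    missing_v <- setdiff(model$variables, colnames(sm))
    if (length(missing_v) > 0) {
      stop("stack lacks model variable(s): ",
           paste(missing_v, collapse = ", "))
    }
    return(sm[, model$variables, drop = FALSE])
  }
  as.matrix(newdata)
}

#' Cloglog suitability prediction
#'
#' `cloglog(x) = 1 - exp(-e^H raw(x))` with H the entropy of the fitted
#' distribution over the training background; values are clamped to
#' \[0, 1\]. For a stack, returns a [raster_grid] with nodata propagated;
#' otherwise a numeric vector.
#'
#' @param model a fitted `maxent_model`.
#' @param newdata a [scenario_stack], raw-variable matrix, or `NULL` for
#'   the training background.
#' @return [raster_grid] or numeric vector of suitabilities in \[0, 1\].
#' @export
predict_cloglog <- function(model, newdata = NULL) {
  raw <- predict_raw(model, newdata)
  cl <- pmin(pmax(1 - exp(-exp(model$H) * raw), 0), 1)
  if (inherits(newdata, "scenario_stack")) {
    ref <- newdata$layers[[1]]
    sm <- stack_matrix(newdata)
    cells <- attr(sm, "cells")
    v <- matrix(NA_real_, ref$nrows, ref$ncols)
    v[cbind(cells[, 1], cells[, 2])] <- cl
    return(raster_grid(v, xll = ref$xll, yll = ref$yll,
                       cellsize = ref$cellsize, nodata = ref$nodata,
                       name = "cloglog"))
  }
  cl
}

#' Regularized training gain
#'
#' Mean presence log raw-likelihood improvement over the uniform background
#' distribution: `gain = mean(ln raw(presence)) + ln(N_background)`
#' (regularization excluded). Zero for the all-zero model.
#'
#' @param model a fitted `maxent_model`.
#' @return numeric scalar.
#' @export
training_gain <- function(model) {
  mean(model$eta_pres) - model$lnZ + log(model$n_bg)
}

#' Jackknife test of variable importance
#'
#' Refits the model with each variable alone and with each variable
#' excluded, reporting training gains against the all-variable model. A
#' variable whose exclusion depresses the gain carries information not
#' supplied by the others.
#'
#' @param presence,background raw-variable matrices.
#' @param config a [feature_config].
#' @param max_iter,tol passed to [fit_maxent()].
#' @return list with `all_gain` and a data.frame `gains` of
#'   (variable, only, without).
#' @export
jackknife_gains <- function(presence, background, config = feature_config(),
                            max_iter = 500, tol = 1e-5) {
  vars <- colnames(presence)
  fit_gain <- function(v) {
    if (length(v) == 0) return(0)
    fd <- build_features(presence[, v, drop = FALSE],
                         background[, v, drop = FALSE], config)
    training_gain(fit_maxent(fd, max_iter = max_iter, tol = tol))
  }
  all_gain <- fit_gain(vars)
  gains <- data.frame(
    variable = vars,
    only = vapply(vars, function(v) fit_gain(v), 0),
    without = vapply(vars, function(v) fit_gain(setdiff(vars, v)), 0),
    row.names = NULL
  )
  list(all_gain = all_gain, gains = gains)
}

#' Permutation importance of model variables
#'
#' For each variable, its values are permuted across the pooled presence
#' and background rows, the training AUC is recomputed, and the AUC drop
#' (floored at zero, averaged over `n_shuffles`) is normalized across
#' variables to sum to 100.
#'
#' @param model a fitted `maxent_model`.
#' @param seed RNG seed for the shuffles.
#' @param n_shuffles number of permutations per variable.
#' @return named numeric vector of percentages summing to 100 (all zeros,
#'   with a warning, if no variable affects the model).
#' @export
permutation_importance <- function(model, seed = 1, n_shuffles = 10) {
  pres <- model$pres_raw
  bg <- model$bg_raw
  m <- nrow(pres)
  pool <- rbind(pres, bg)
  auc_full <- auc(model_eta(model, pres), model_eta(model, bg))
  drops <- with_seed(seed, {
    vapply(model$variables, function(v) {
      mean(vapply(seq_len(n_shuffles), function(s) {
        perm <- pool
        perm[, v] <- sample(perm[, v])
        eta <- model_eta(model, perm)
        auc_full - auc(eta[seq_len(m)], eta[-seq_len(m)])
      }, 0))
    }, 0)
  })
  drops <- pmax(drops, 0)
  tot <- sum(drops)
  if (tot <= 0) {
    warning("no variable affects the model; permutation importance undefined")
    return(stats::setNames(numeric(length(model$variables)),
                           model$variables))
  }
  100 * drops / tot
}

#' Percent contribution of model variables
#'
#' Path-dependent attribution: every accepted coordinate-descent update
#' credits the change in the unpenalized objective to the updated feature's
#' variable (split evenly for product features); tallies are normalized to
#' sum to 100.
#'
#' @param model a fitted `maxent_model`.
#' @return named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model) {
  t <- model$contribution_tally[model$variables]
  names(t) <- model$variables
  t[is.na(t)] <- 0
  tot <- sum(t)
  if (tot <= 0) {
    return(stats::setNames(numeric(length(model$variables)),
                           model$variables))
  }
  100 * t / tot
}

#' Response curve of one variable
#'
#' Evaluates the model while one variable sweeps its background range
#' (endpoints exactly the background min/max) and all others are held at
#' their background means.
#'
#' @param model a fitted `maxent_model`.
#' @param variable variable code.
#' @param n_points number of evaluation points.
#' @return data.frame with columns `value` and `cloglog`.
#' @export
response_curve <- function(model, variable, n_points = 100) {
  if (!variable %in% model$variables) {
    stop(sprintf("'%s' is not a model variable", variable))
  }
  i <- match(variable, model$scaling$var)
  vals <- seq(model$scaling$min[i], model$scaling$max[i],
              length.out = n_points)
  means <- colMeans(model$bg_raw)
  raw <- matrix(rep(means, each = n_points), nrow = n_points,
                dimnames = list(NULL, model$variables))
  raw[, variable] <- vals
  data.frame(value = vals, cloglog = predict_cloglog(model, raw))
}

#' Serialize a fitted model to a plain-text file
#'
#' Writes one JSON document holding the per-feature weight table
#' (feature, lambda, and the variable's background min/max) and a metadata
#' block (lnZ, entropy, configuration, convergence).
#'
#' @param model a fitted `maxent_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maxent_model <- function(model, path) {
  i <- match(model$defs$var1, model$scaling$var)
  obj <- list(
    lambdas = data.frame(feature = model$defs$feature,
                         lambda = unname(model$lambda),
                         class = model$defs$class,
                         var1 = model$defs$var1, var2 = model$defs$var2,
                         knot = model$defs$knot,
                         min = model$scaling$min[i],
                         max = model$scaling$max[i]),
    scaling = model$scaling,
    meta = list(lnZ = model$lnZ, H = model$H, rm = model$rm,
                fc = model$config$fc,
                hinge_knots = model$config$hinge_knots,
                threshold_knots = model$config$threshold_knots,
                m = model$m, n_bg = model$n_bg,
                variables = model$variables,
                convergence = model$convergence)
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              na = "null"), path)
  invisible(path)
}

#' Read a serialized model
#'
#' Restores enough of a [write_maxent_model()] file to predict over new
#' scenarios (weights, feature definitions, scaling, lnZ, entropy).
#'
#' @param path file written by [write_maxent_model()].
#' @return A `maxent_model` (without training data; importance measures
#'   that need the training rows are unavailable on a restored model).
#' @export
read_maxent_model <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"))
  defs <- obj$lambdas[, c("feature", "class", "var1", "var2", "knot")]
  defs$var2 <- ifelse(is.na(defs$var2) | defs$var2 == "NA",
                      NA_character_, defs$var2)
  structure(
    list(lambda = stats::setNames(obj$lambdas$lambda, obj$lambdas$feature),
         defs = defs, scaling = obj$scaling,
         config = feature_config(obj$meta$fc, obj$meta$rm,
                                 obj$meta$hinge_knots,
                                 obj$meta$threshold_knots),
         rm = obj$meta$rm, lnZ = obj$meta$lnZ, H = obj$meta$H,
         m = obj$meta$m, n_bg = obj$meta$n_bg,
         variables = obj$meta$variables,
         convergence = obj$meta$convergence),
    class = "maxent_model"
  )
}
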