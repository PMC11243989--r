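#' Default 46-layer environmental variable specification
#'
#' Mirrors the composition of a typical protected-area predictor set:
#' 19 bioclimatic layers (`BIO1`--`BIO19`), 11 edaphic layers
#' (`SOIL1`--`SOIL11`), 3 topographic layers (`ELV`, `SLP`, `ASP`),
#' 12 land-cover layers (`LC1`--`LC12`) and one cumulative human-pressure
#' layer (`CHP`). Climate and soil layers vary smoothly (longer spatial
#' correlation length); land cover and human pressure are patchier.
#'
#' @return data.frame with columns `name`, `class`
#'   (climate/soil/topographic/landcover/human) and `smoothing`
#'   (isotropic kernel length in cells).
#' @export
default_layer_spec <- function() {
  rbind(
    data.frame(name = paste0("BIO", 1:19), class = "climate", smoothing = 4),
    data.frame(name = paste0("SOIL", 1:11), class = "soil", smoothing = 3),
    data.frame(name = c("ELV", "SLP", "ASP"), class = "topographic",
               smoothing = c(5, 2, 2)),
    data.frame(name = paste0("LC", 1:12), class = "landcover", smoothing = 1.5),
    data.frame(name = "CHP", class = "human", smoothing = 2)
  )
}

# smooth a white-noise matrix with a separable Gaussian kernel (sd = len
# cells); len 0 returns the noise untouched. Edges handled by renormalizing
# the kernel mass actually inside the grid.
smooth_field <- function(noise, len) {
  if (len <= 0) return(noise)
  half <- max(1L, ceiling(3 * len))
  k <- stats::dnorm(seq(-half, half), sd = len)
  k <- k / sum(k)
  ones <- matrix(1, nrow(noise), ncol(noise))
  conv1 <- function(m) {
    # zero-pad so the kernel never runs off the vector, then renormalize by
    # the kernel mass actually inside the grid (the smoothed ones field)
    f <- function(v) {
      n <- length(v)
      vp <- c(rep(0, half), v, rep(0, half))
      out <- stats::filter(vp, k, sides = 2)
      as.numeric(out[(half + 1):(half + n)])
    }
    a <- apply(m, 2, f)
    t(apply(t(a), 2, f))
  }
  num <- conv1(noise)
  den <- conv1(ones)
  num / den
}

# default octagonal study-area mask: clip 6 cells from each corner
default_mask <- function(nrows, ncols) {
  m <- matrix(FALSE, nrows, ncols)
  for (i in seq_len(nrows)) {
    for (j in seq_len(ncols)) {
      d <- min((i - 1) + (j - 1),
               (i - 1) + (ncols - j),
               (nrows - i) + (j - 1),
               (nrows - i) + (ncols - j))
      if (d < 3) m[i, j] <- TRUE
    }
  }
  m
}

#' Generate a synthetic environmental scenario stack
#'
#' Each layer is a Gaussian random field: white noise convolved with an
#' isotropic Gaussian kernel of the layer's smoothing length, then
#' standardized to mean 0 / sd 1 over usable cells. If `target_corr` is
#' given, the independent fields are first orthogonalized empirically and
#' then linearly mixed by the Cholesky (or eigen square root) factor of the
#' target matrix, so empirical pairwise correlations approach the targets.
#'
#' @param seed RNG seed; generation is a pure function of
#'   `(seed, parameters)`.
#' @param nrows,ncols grid dimensions (both at least 8). Default 25 x 25,
#'   the scale of a small protected area at 30 arc-second resolution.
#' @param layer_spec data.frame as [default_layer_spec()].
#' @param target_corr optional symmetric positive semi-definite correlation
#'   matrix (dimension = number of layers, in `layer_spec` order).
#' @param mask logical matrix (`TRUE` = masked/outside) or `NULL` for the
#'   default corner-clipped study area, or `FALSE` for no mask.
#' @param xll,yll,cellsize grid registration (degrees); defaults place the
#'   grid in the northern Apennines at 30 arc-seconds.
#' @param label scenario label.
#' @return A [scenario_stack].
#' @export
gen_stack <- function(seed, nrows = 25, ncols = 25,
                      layer_spec = default_layer_spec(),
                      target_corr = NULL, mask = NULL,
                      xll = 11.7, yll = 43.7, cellsize = 1 / 120,
                      label = "current") {
  stopifnot(nrows >= 8, ncols >= 8, nrow(layer_spec) >= 1)
  k <- nrow(layer_spec)
  if (!is.null(target_corr)) {
    if (!is.matrix(target_corr) || any(dim(target_corr) != k)) {
      stop("target_corr must be a k x k matrix matching layer_spec")
    }
    if (max(abs(target_corr - t(target_corr))) > 1e-8) {
      stop("target_corr must be symmetric")
    }
    ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("target_corr is not positive semi-definite (min eigenvalue ",
           format(min(ev)), ")")
    }
  }
  if (is.null(mask)) {
    mk <- default_mask(nrows, ncols)
  } else if (isFALSE(mask)) {
    mk <- matrix(FALSE, nrows, ncols)
  } else {
    stopifnot(is.matrix(mask), all(dim(mask) == c(nrows, ncols)))
    mk <- mask
  }
  usable <- which(!mk)
  fields <- with_seed(seed, {
    vapply(seq_len(k), function(i) {
      f <- smooth_field(matrix(stats::rnorm(nrows * ncols), nrows, ncols),
                        layer_spec$smoothing[i])
      as.numeric(f)
    }, numeric(nrows * ncols))
  })
  # standardize over usable cells
  fu <- fields[usable, , drop = FALSE]
  fu <- scale(fu)
  if (!is.null(target_corr)) {
    # empirical orthonormalization, then mix to the target correlation
    qr_ <- qr(scale(fu, scale = FALSE))
    q <- qr.Q(qr_)[, seq_len(k), drop = FALSE]
    # keep each orthogonal column pointing the way of its source field
    sgn <- sign(diag(qr.R(qr_)))
    sgn[sgn == 0] <- 1
    q <- sweep(q, 2, sgn, `*`)
    z <- q * sqrt(nrow(q) - 1)
    ee <- eigen(target_corr, symmetric = TRUE)
    rt <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), k) %*% t(ee$vectors)
    fu <- z %*% rt
  }
  layers <- vector("list", k)
  for (i in seq_len(k)) {
    v <- matrix(NA_real_, nrows, ncols)
    v[usable] <- fu[, i]
    layers[[i]] <- raster_grid(v, xll = xll, yll = yll, cellsize = cellsize,
                               name = layer_spec$name[i])
  }
  names(layers) <- layer_spec$name
  scenario_stack(layers, label = label)
}

#' Build a known true suitability surface over a stack
#'
#' The surface is the inverse logit of a linear predictor with optional
#' per-layer linear and quadratic terms, used as ground truth for
#' parameter-recovery experiments. Deterministic (no RNG).
#'
#' @param stack a [scenario_stack].
#' @param coefficients named numeric vector of linear weights (names are
#'   layer codes), or a list with elements `linear` and `quadratic`, each a
#'   named vector.
#' @param intercept scalar intercept.
#' @return list of class `true_suitability` with `coefficients`,
#'   `intercept` and `surface` (a [raster_grid] with values in \[0, 1\]).
#' @export
gen_true_suitability <- function(stack, coefficients, intercept = 0) {
  if (!is.list(coefficients)) {
    coefficients <- list(linear = coefficients,
                         quadratic = stats::setNames(numeric(0), character(0)))
  }
  lin <- coefficients$linear %||% stats::setNames(numeric(0), character(0))
  qua <- coefficients$quadratic %||% stats::setNames(numeric(0), character(0))
  unknown <- setdiff(c(names(lin), names(qua)), names(stack$layers))
  if (length(unknown) > 0) {
    stop("coefficients name layers not in the stack: ",
         paste(unknown, collapse = ", "))
  }
  ref <- stack$layers[[1]]
  eta <- matrix(intercept, ref$nrows, ref$ncols)
  for (nm in names(lin)) eta <- eta + lin[[nm]] * stack$layers[[nm]]$values
  for (nm in names(qua)) eta <- eta + qua[[nm]] * stack$layers[[nm]]$values^2
  s <- stats::plogis(eta)
  s <- pmin(pmax(s, 0), 1)
  s[is.na(ref$values)] <- NA_real_
  structure(
    list(coefficients = coefficients, intercept = intercept,
         surface = raster_grid(s, xll = ref$xll, yll = ref$yll,
                               cellsize = ref$cellsize, name = "true_suit")),
    class = "true_suitability"
  )
}

#' Sample presence points from a true suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability; each point is then placed uniformly at random within its
#' cell, emulating GPS-located field records.
#'
#' @param true_suit a `true_suitability` object (or a [raster_grid] of
#'   suitabilities).
#' @param n number of presence points.
#' @param seed RNG seed.
#' @param species species label attached to the records.
#' @return An [occurrence_set] with provenance `"raw"`.
#' @export
sample_occurrences <- function(true_suit, n, seed, species = "synthetic_sp") {
  surf <- if (inherits(true_suit, "true_suitability")) true_suit$surface
          else true_suit
  stopifnot(inherits(surf, "raster_grid"), n >= 1)
  s <- surf$values
  pos <- which(!is.na(s) & s > 0)
  if (length(pos) == 0) stop("no non-masked cell has positive suitability")
  if (n > length(pos)) {
    stop(sprintf("n = %d exceeds the %d cells with positive suitability",
                 n, length(pos)))
  }
  with_seed(seed, {
    cells <- pos[sample.int(length(pos), n, replace = FALSE, prob = s[pos])]
    idx <- arrayInd(cells, dim(s))
    # cell (row i, col j): x in [xll+(j-1)cs, xll+j cs), y measured from south
    u <- stats::runif(n); v <- stats::runif(n)
    lon <- surf$xll + (idx[, 2] - 1 + u) * surf$cellsize
    lat <- surf$yll + (surf$nrows - idx[, 1] + v) * surf$cellsize
    occurrence_set(species = species, lon = lon, lat = lat,
                   provenance = "raw")
  })
}

#' Perturb the climate layers of a stack into a future scenario
#'
#' Adds a per-layer constant shift plus a spatially smooth Gaussian noise
#' field to the named bioclimatic layers; all other layers are carried over
#' bit-identically, reflecting the assumption that only climate changes.
#'
#' @param current a [scenario_stack].
#' @param deltas data.frame with columns `name` (must be `BIO*` layers),
#'   `shift` (additive change) and `sd` (sd of the smooth noise field).
#' @param seed RNG seed.
#' @param label label of the future stack, e.g. `"2050s-SSP585"`.
#' @param noise_smoothing kernel length (cells) for the noise field.
#' @return A [scenario_stack].
#' @export
gen_future_stack <- function(current, deltas, seed, label,
                             noise_smoothing = 3) {
  stopifnot(inherits(current, "scenario_stack"),
            is.data.frame(deltas),
            all(c("name", "shift", "sd") %in% names(deltas)))
  bad <- deltas$name[!grepl("^BIO[0-9]+$", deltas$name)]
  if (length(bad) > 0) {
    stop("deltas may only name bioclimatic (BIO*) layers; got: ",
         paste(bad, collapse = ", "))
  }
  missing_l <- setdiff(deltas$name, names(current$layers))
  if (length(missing_l) > 0) {
    stop("deltas name layers absent from the stack: ",
         paste(missing_l, collapse = ", "))
  }
  ref <- current$layers[[1]]
  layers <- current$layers
  with_seed(seed, {
    for (i in seq_len(nrow(deltas))) {
      nm <- deltas$name[i]
      l <- layers[[nm]]
      noise <- 0
      if (deltas$sd[i] > 0) {
        f <- smooth_field(matrix(stats::rnorm(ref$nrows * ref$ncols),
                                 ref$nrows, ref$ncols), noise_smoothing)
        f <- (f - mean(f)) / stats::sd(f)
        noise <- deltas$sd[i] * f
      }
      l$values <- l$values + deltas$shift[i] + noise
      layers[[nm]] <- l
    }
  })
  scenario_stack(layers, label = label)
}
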