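#' Feature-class configuration for the maximum-entropy model
#'
#' @param fc feature-class string, a non-empty subset of `"LQHPT"`
#'   (Linear, Quadratic, Hinge, Product, Threshold).
#' @param rm regularization multiplier (> 0); scales every per-feature
#'   penalty weight.
#' @param hinge_knots,threshold_knots number of interior knots per variable
#'   for hinge and threshold features.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(fc = "LQHPT", rm = 1, hinge_knots = 15,
                           threshold_knots = 15) {
  fc <- toupper(fc)
  cls <- strsplit(fc, "")[[1]]
  if (length(cls) == 0 || !all(cls %in% c("L", "Q", "H", "P", "T"))) {
    stop("fc must be a non-empty subset of 'LQHPT'")
  }
  if (rm <= 0) stop("rm must be positive")
  structure(list(fc = fc, rm = rm, hinge_knots = hinge_knots,
                 threshold_knots = threshold_knots),
            class = "feature_config")
}

# table of feature definitions for a variable set under a config;
# knots live on the background-scaled [0,1] axis
make_feature_defs <- function(vars, config) {
  cls <- strsplit(config$fc, "")[[1]]
  defs <- list()
  add <- function(feature, class, var1, var2 = NA_character_,
                  knot = NA_real_) {
    defs[[length(defs) + 1]] <<- data.frame(
      feature = feature, class = class, var1 = var1, var2 = var2,
      knot = knot, stringsAsFactors = FALSE)
  }
  if ("L" %in% cls) for (v in vars) add(paste0("L:", v), "L", v)
  if ("Q" %in% cls) for (v in vars) add(paste0("Q:", v), "Q", v)
  if ("P" %in% cls && length(vars) >= 2) {
    cmb <- utils::combn(vars, 2)
    for (i in seq_len(ncol(cmb))) {
      add(paste0("P:", cmb[1, i], ":", cmb[2, i]), "P", cmb[1, i], cmb[2, i])
    }
  }
  if ("H" %in% cls && config$hinge_knots > 0) {
    ks <- seq(0, 1, length.out = config$hinge_knots + 2)
    ks <- ks[-c(1, length(ks))]
    for (v in vars) for (k in ks) {
      add(sprintf("HF:%s:%.6f", v, k), "HF", v, knot = k)
      add(sprintf("HR:%s:%.6f", v, k), "HR", v, knot = k)
    }
  }
  if ("T" %in% cls && config$threshold_knots > 0) {
    ks <- seq(0, 1, length.out = config$threshold_knots + 2)
    ks <- ks[-c(1, length(ks))]
    for (v in vars) for (k in ks) {
      add(sprintf("T:%s:%.6f", v, k), "T", v, knot = k)
    }
  }
  do.call(rbind, defs)
}

# evaluate the feature design for raw-variable rows; scaling is the
# data.frame(var, min, max) frozen from the training background
feature_rows <- function(defs, scaling, raw) {
  raw <- as.matrix(raw)
  sc <- function(v) {
    i <- match(v, scaling$var)
    (raw[, v] - scaling$min[i]) / (scaling$max[i] - scaling$min[i])
  }
  out <- matrix(0, nrow(raw), nrow(defs),
                dimnames = list(NULL, defs$feature))
  for (j in seq_len(nrow(defs))) {
    d <- defs[j, ]
    x <- sc(d$var1)
    out[, j] <- switch(d$class,
      L = x,
      Q = x^2,
      P = x * sc(d$var2),
      HF = pmax(0, (x - d$knot) / (1 - d$knot)),
      HR = pmax(0, (d$knot - x) / d$knot),
      T = as.numeric(x > d$knot)
    )
  }
  out
}

#' Build the presence/background feature design
#'
#' Raw variables are scaled to \[0, 1\] by their background min/max (the
#' scaling is frozen into the design and reused verbatim when projecting to
#' other scenarios). Classes: linear `x`; quadratic `x^2`; product
#' `x_i x_j` over all pairs; forward/reverse hinges
#' `max(0, (x - k)/(1 - k))` and `max(0, (k - x)/k)` at evenly spaced
#' interior knots; threshold indicators `x > k`. Zero-variance variables
#' are dropped from the design with a warning.
#'
#' @param presence,background raw-variable matrices (rows x variables) with
#'   identical column names.
#' @param config a [feature_config].
#' @return list of class `feature_design` with elements `pres`, `bg`
#'   (feature matrices), `defs`, `scaling`, `config`, `pres_raw`, `bg_raw`.
#' @export
build_features <- function(presence, background, config = feature_config()) {
  presence <- as.matrix(presence)
  background <- as.matrix(background)
  if (!identical(colnames(presence), colnames(background))) {
    stop("presence and background must have identical variable columns")
  }
  vars <- colnames(presence)
  mins <- apply(background, 2, min)
  maxs <- apply(background, 2, max)
  degenerate <- vars[maxs - mins <= 0]
  if (length(degenerate) > 0) {
    warning("zero-variance variable(s) dropped from the feature design: ",
            paste(degenerate, collapse = ", "))
    vars <- setdiff(vars, degenerate)
    if (length(vars) == 0) stop("no variable with positive variance")
  }
  scaling <- data.frame(var = vars, min = mins[vars], max = maxs[vars],
                        row.names = NULL)
  defs <- make_feature_defs(vars, config)
  structure(
    list(pres = feature_rows(defs, scaling, presence[, vars, drop = FALSE]),
         bg = feature_rows(defs, scaling, background[, vars, drop = FALSE]),
         defs = defs, scaling = scaling, config = config,
         pres_raw = presence[, vars, drop = FALSE],
         bg_raw = background[, vars, drop = FALSE]),
    class = "feature_design"
  )
}
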