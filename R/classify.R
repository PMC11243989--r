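#' Maximum test sensitivity plus specificity threshold
#'
#' Per replicate, candidate thresholds sweep the union of observed test
#' presence and background scores; sensitivity is the fraction of test
#' presences at or above the candidate and specificity the fraction of
#' background cells below it. The per-replicate maximizer (lowest candidate
#' on ties) is averaged over replicates and reported to 4 decimals.
#'
#' @param test_scores list of per-replicate test presence score vectors
#'   (or a single numeric vector).
#' @param background_scores list of per-replicate background score vectors
#'   (or a single vector recycled across replicates).
#' @return threshold `t` in (0, 1).
#' @export
mtsps_threshold <- function(test_scores, background_scores) {
  if (!is.list(test_scores)) test_scores <- list(test_scores)
  if (!is.list(background_scores)) {
    background_scores <- rep(list(background_scores), length(test_scores))
  }
  stopifnot(length(test_scores) == length(background_scores),
            all(vapply(test_scores, length, 0L) >= 1))
  per_rep <- vapply(seq_along(test_scores), function(r) {
    te <- test_scores[[r]]; bg <- background_scores[[r]]
    cand <- sort(unique(c(te, bg)))
    ss <- vapply(cand, function(t) {
      mean(te >= t) + mean(bg < t)
    }, 0)
    cand[which(ss >= max(ss) - 1e-12)[1]]
  }, 0)
  round_half_up(mean(per_rep), 4)
}

#' Classify a suitability map into four classes
#'
#' Cells below the threshold are unsuitable (0); the suitable range
#' \[t, 1\] is cut into three equal-width classes: low (1) on
#' \[t, b1), moderate (2) on \[b1, b2), high (3) on \[b2, 1\], with
#' `b1 = t + (1 - t)/3` and `b2 = t + 2(1 - t)/3`. Lower-closed,
#' upper-open; the top class is closed at 1.
#'
#' @param map a [raster_grid] of suitabilities in \[0, 1\].
#' @param t threshold in (0, 1), typically from [mtsps_threshold()].
#' @param cell_area_km2 area of one cell in square kilometres.
#' @return list of class `classified_map`: `grid` (integer-coded
#'   [raster_grid]), `threshold`, boundaries `b1`, `b2`, and a per-class
#'   `counts` data.frame (class, cells, km2).
#' @export
classify <- function(map, t, cell_area_km2 = 25 / 36) {
  stopifnot(inherits(map, "raster_grid"), t > 0, t < 1)
  b1 <- t + (1 - t) / 3
  b2 <- t + 2 * (1 - t) / 3
  p <- map$values
  cls <- ifelse(p < t, 0L, ifelse(p < b1, 1L, ifelse(p < b2, 2L, 3L)))
  cls[is.na(p)] <- NA_integer_
  cells <- vapply(0:3, function(k) sum(cls == k, na.rm = TRUE), 0L)
  counts <- data.frame(
    class = c("unsuitable", "low", "moderate", "high"),
    code = 0:3, cells = cells,
    km2 = round_half_up(cells * cell_area_km2, 2)
  )
  structure(
    list(grid = raster_grid(cls, xll = map$xll, yll = map$yll,
                            cellsize = map$cellsize, nodata = map$nodata,
                            name = "class"),
         threshold = t,
         b1 = round_half_up(b1, 4), b2 = round_half_up(b2, 4),
         b1_exact = b1, b2_exact = b2,
         cell_area_km2 = cell_area_km2,
         counts = counts),
    class = "classified_map"
  )
}

#' @export
print.classified_map <- function(x, ...) {
  cat(sprintf("<classified_map> t = %.4f, b1 = %.4f, b2 = %.4f\n",
              x$threshold, x$b1, x$b2))
  print(x$counts)
  invisible(x)
}

#' Binarize a suitability map at a threshold
#'
#' Suitable (1) iff `p >= t`; nodata propagated.
#'
#' @param map a [raster_grid] of suitabilities.
#' @param t threshold in (0, 1).
#' @return A \{0, 1\}-valued [raster_grid].
#' @export
binary_map <- function(map, t) {
  stopifnot(inherits(map, "raster_grid"), t > 0, t < 1)
  v <- ifelse(map$values >= t, 1, 0)
  v[is.na(map$values)] <- NA_real_
  raster_grid(v, xll = map$xll, yll = map$yll, cellsize = map$cellsize,
              nodata = map$nodata, name = "binary")
}

#' Species range change between two binary maps
#'
#' Cross-tabulates aligned current/future presence-absence maps into loss
#' (1 to 0), stable (1 to 1) and gain (0 to 1) cells, and derives
#' `%Loss = 100 Loss/(Loss + Stable)`, `%Gain = 100 Gain/(Loss + Stable)`,
#' `SRC = %Gain - %Loss` and the Current Range Size
#' `CRS = Loss + Stable`, with square-kilometre equivalents. Percentages
#' are reported at 2 decimals; the SRC identity holds exactly before
#' rounding.
#'
#' @param current_binary,future_binary \{0, 1\} [raster_grid]s with
#'   identical headers and masks.
#' @param cell_area_km2 area of one cell.
#' @return list of class `range_change_result`.
#' @export
range_change <- function(current_binary, future_binary,
                         cell_area_km2 = 25 / 36) {
  stopifnot(inherits(current_binary, "raster_grid"),
            inherits(future_binary, "raster_grid"))
  if (!grid_header_equal(current_binary, future_binary)) {
    stop("current and future binary maps are not aligned")
  }
  cur <- current_binary$values
  fut <- future_binary$values
  if (!identical(is.na(cur), is.na(fut))) {
    stop("current and future masks differ")
  }
  loss <- sum(cur == 1 & fut == 0, na.rm = TRUE)
  stable <- sum(cur == 1 & fut == 1, na.rm = TRUE)
  gain <- sum(cur == 0 & fut == 1, na.rm = TRUE)
  crs <- loss + stable
  pl <- if (crs > 0) 100 * loss / crs else NA_real_
  pg <- if (crs > 0) 100 * gain / crs else NA_real_
  src <- if (crs > 0) pg - pl else NA_real_
  structure(
    list(loss = loss, stable = stable, gain = gain, crs = crs,
         pct_loss = round_half_up(pl, 2),
         pct_gain = round_half_up(pg, 2),
         src = round_half_up(src, 2),
         pct_loss_exact = pl, pct_gain_exact = pg, src_exact = src,
         cell_area_km2 = cell_area_km2,
         loss_km2 = round_half_up(loss * cell_area_km2, 2),
         stable_km2 = round_half_up(stable * cell_area_km2, 2),
         gain_km2 = round_half_up(gain * cell_area_km2, 2),
         crs_km2 = round_half_up(crs * cell_area_km2, 2)),
    class = "range_change_result"
  )
}

#' @export
print.range_change_result <- function(x, ...) {
  cat(sprintf(paste0("<range_change_result> loss %d, stable %d, gain %d ",
                     "(CRS %d cells = %.2f km2)\n  %%Loss %.2f, %%Gain %.2f, ",
                     "SRC %.2f\n"),
              x$loss, x$stable, x$gain, x$crs, x$crs_km2,
              x$pct_loss, x$pct_gain, x$src))
  invisible(x)
}

#' Per-class area accounting across scenarios
#'
#' For each scenario's classified map: cells per class, square kilometres
#' (2 decimals), percent of the total study area, and the percent increase
#' or decrease of each class relative to the present scenario, computed on
#' integer cell counts. A class empty at present with future cells yields
#' `NA` change and a flag.
#'
#' @param classified named list of `classified_map`s; must include
#'   `present`.
#' @param cell_area_km2 area of one cell.
#' @return data.frame with one row per scenario x class.
#' @export
area_summary <- function(classified, cell_area_km2 = 25 / 36) {
  stopifnot("present" %in% names(classified))
  total <- sum(classified$present$counts$cells)
  present_cells <- stats::setNames(classified$present$counts$cells,
                                   classified$present$counts$class)
  rows <- lapply(names(classified), function(sc) {
    cnt <- classified[[sc]]$counts
    chg <- vapply(seq_len(nrow(cnt)), function(i) {
      p <- present_cells[[cnt$class[i]]]
      if (sc == "present") return(NA_real_)
      if (p == 0) return(NA_real_)
      round_half_up(100 * (cnt$cells[i] - p) / p, 2)
    }, 0)
    data.frame(scenario = sc, class = cnt$class, cells = cnt$cells,
               km2 = round_half_up(cnt$cells * cell_area_km2, 2),
               pct_of_total = round_half_up(100 * cnt$cells / total, 2),
               pct_change_vs_present = chg,
               undefined_change = sc != "present" &
                 present_cells[cnt$class] == 0 & cnt$cells > 0)
  })
  do.call(rbind, rows)
}
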