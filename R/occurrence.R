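#' Species occurrence records
#'
#' A set of WGS84 presence points for one species, with a provenance flag
#' tracking the preparation stage (`raw` -> `deduped` -> `clipped` ->
#' `thinned`).
#'
#' @param species species label.
#' @param lon,lat numeric vectors of coordinates (decimal degrees, WGS84).
#' @param provenance one of `"raw"`, `"deduped"`, `"clipped"`, `"thinned"`.
#' @param thin_par_km thinning distance used, if provenance is `"thinned"`.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, lon, lat, provenance = "raw",
                           thin_par_km = NULL) {
  stopifnot(length(lon) == length(lat),
            provenance %in% c("raw", "deduped", "clipped", "thinned"))
  structure(
    list(species = species,
         points = data.frame(lon = as.numeric(lon), lat = as.numeric(lat)),
         provenance = provenance,
         thin_par_km = thin_par_km),
    class = "occurrence_set"
  )
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d points (%s)\n", x$species,
              nrow(x$points), x$provenance))
  invisible(x)
}

#' Number of points in an occurrence set
#' @param occ an [occurrence_set].
#' @return integer count.
#' @export
n_points <- function(occ) nrow(occ$points)

#' Read occurrence records from CSV
#'
#' Expects columns `species,lon,lat`. If `species` is given only that
#' species' records are returned.
#'
#' @param path CSV file path.
#' @param species optional species filter.
#' @return An [occurrence_set] (single species) or a named list of them.
#' @export
read_occurrences <- function(path, species = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "lon", "lat") %in% names(df))) {
    stop("occurrence CSV needs columns species,lon,lat")
  }
  if (!is.null(species)) {
    df <- df[df$species == species, , drop = FALSE]
    if (nrow(df) == 0) stop(sprintf("species '%s' not found in '%s'",
                                    species, path))
    return(occurrence_set(species, df$lon, df$lat))
  }
  sp <- unique(df$species)
  stats::setNames(lapply(sp, function(s) {
    d <- df[df$species == s, ]
    occurrence_set(s, d$lon, d$lat)
  }), sp)
}

#' Write occurrence records to CSV
#' @param occ an [occurrence_set] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  if (inherits(occ, "occurrence_set")) occ <- list(occ)
  df <- do.call(rbind, lapply(occ, function(o) {
    data.frame(species = o$species, lon = o$points$lon, lat = o$points$lat)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove exact-coordinate duplicate records
#'
#' The first record of each duplicated coordinate pair is kept; order is
#' otherwise preserved. No snapping tolerance is applied.
#'
#' @param occ an [occurrence_set].
#' @return An [occurrence_set] with provenance `"deduped"`.
#' @export
deduplicate <- function(occ) {
  stopifnot(inherits(occ, "occurrence_set"))
  keep <- !duplicated(occ$points[, c("lon", "lat")])
  occurrence_set(occ$species, occ$points$lon[keep], occ$points$lat[keep],
                 provenance = "deduped")
}

#' Remove records outside the study area
#'
#' A point is retained iff its containing cell (half-open cell convention,
#' see the package vignette) is inside the grid extent and not nodata in
#' the mask.
#'
#' @param occ an [occurrence_set].
#' @param mask a [raster_grid] whose `NA` cells are outside the study area,
#'   or a [scenario_stack] (its first layer's mask is used).
#' @return An [occurrence_set] with provenance `"clipped"`.
#' @export
clip_to_boundary <- function(occ, mask) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (inherits(mask, "scenario_stack")) mask <- mask$layers[[1]]
  stopifnot(inherits(mask, "raster_grid"))
  if (nrow(occ$points) == 0) {
    return(occurrence_set(occ$species, numeric(0), numeric(0), "clipped"))
  }
  rc <- locate_cells(mask, occ$points$lon, occ$points$lat)
  keep <- !is.na(rc[, "row"]) &
    !is.na(mask$values[cbind(rc[, "row"], rc[, "col"])])
  occurrence_set(occ$species, occ$points$lon[keep], occ$points$lat[keep],
                 provenance = "clipped")
}

# great-circle distance matrix in km (haversine, R = 6371 km)
haversine_km <- function(pts) {
  if (nrow(pts) < 2) return(matrix(0, nrow(pts), nrow(pts)))
  geosphere::distm(as.matrix(pts[, c("lon", "lat")]),
                   fun = function(p1, p2) {
                     geosphere::distHaversine(p1, p2, r = 6371000)
                   }) / 1000
}

#' Spatially thin occurrence records
#'
#' Removes points until no pair is closer than `thin_par_km` (great-circle
#' distance). Each randomized run repeatedly deletes one of the points with
#' the greatest number of too-close neighbours (ties broken uniformly at
#' random); among `reps` runs, one retaining the maximum number of points
#' is returned. This reduces spatial sampling bias before model fitting.
#'
#' @param occ an [occurrence_set].
#' @param thin_par_km minimum nearest-neighbour distance to enforce (km).
#' @param reps number of randomized runs.
#' @param seed RNG seed.
#' @param log_path optional CSV path; per-run retained counts are appended
#'   for audit.
#' @return An [occurrence_set] with provenance `"thinned"`.
#' @export
spatial_thin <- function(occ, thin_par_km = 1.0, reps = 100, seed = 1,
                         log_path = NULL) {
  stopifnot(inherits(occ, "occurrence_set"), reps >= 1)
  if (thin_par_km <= 0) stop("thin_par_km must be positive")
  n <- nrow(occ$points)
  if (n <= 1) {
    return(occurrence_set(occ$species, occ$points$lon, occ$points$lat,
                          "thinned", thin_par_km))
  }
  d <- haversine_km(occ$points)
  close <- d < thin_par_km
  diag(close) <- FALSE
  runs <- with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      alive <- rep(TRUE, n)
      cl <- close
      repeat {
        counts <- rowSums(cl[, alive, drop = FALSE]) * alive
        mx <- max(counts)
        if (mx == 0) break
        worst <- which(counts == mx)
        drop_i <- if (length(worst) == 1) worst else sample(worst, 1)
        alive[drop_i] <- FALSE
        cl[drop_i, ] <- FALSE
        cl[, drop_i] <- FALSE
      }
      alive
    })
  })
  kept <- vapply(runs, sum, 0L)
  best <- runs[[which.max(kept)]]
  if (!is.null(log_path)) {
    utils::write.csv(
      data.frame(run = seq_len(reps), retained = kept, removed = n - kept),
      log_path, row.names = FALSE, quote = FALSE
    )
  }
  occurrence_set(occ$species, occ$points$lon[best], occ$points$lat[best],
                 "thinned", thin_par_km)
}

#' Minimum pairwise great-circle distance of an occurrence set (km)
#' @param occ an [occurrence_set].
#' @return numeric (Inf for fewer than 2 points).
#' @export
min_pair_distance_km <- function(occ) {
  n <- nrow(occ$points)
  if (n < 2) return(Inf)
  d <- haversine_km(occ$points)
  min(d[upper.tri(d)])
}

#' Extract the per-point environmental data matrix
#'
#' Combines each occurrence record with the value of every layer at its
#' containing cell. Points falling on masked or outside cells are an error:
#' clip first.
#'
#' @param occ an [occurrence_set] (ideally clipped).
#' @param stack a [scenario_stack].
#' @return matrix (points x layers) of class `occurrence_matrix`, with the
#'   species label as attribute `species`.
#' @export
extract_matrix <- function(occ, stack) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(stack, "scenario_stack"))
  ref <- stack$layers[[1]]
  rc <- locate_cells(ref, occ$points$lon, occ$points$lat)
  if (any(is.na(rc[, "row"]))) {
    stop("occurrence points fall outside the grid extent; clip first")
  }
  m <- vapply(stack$layers, function(l) {
    l$values[cbind(rc[, "row"], rc[, "col"])]
  }, numeric(nrow(occ$points)))
  m <- matrix(m, nrow = nrow(occ$points),
              dimnames = list(NULL, names(stack$layers)))
  if (anyNA(m)) stop("occurrence points fall on masked cells; clip first")
  attr(m, "species") <- occ$species
  attr(m, "cells") <- rc
  class(m) <- c("occurrence_matrix", class(m))
  m
}
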