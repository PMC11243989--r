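#' Single-band raster grid
#'
#' Lightweight in-memory raster with ESRI ASCII grid semantics: lower-left
#' corner registration, square cells in decimal degrees, a nodata sentinel.
#' Values are stored as a `nrows x ncols` matrix with row 1 the northmost
#' row; missing cells are `NA` internally and only become the sentinel on
#' write.
#'
#' @param values numeric matrix, row 1 = north.
#' @param xll,yll longitude/latitude of the lower-left corner (degrees).
#' @param cellsize cell edge length (degrees).
#' @param nodata sentinel written for missing cells.
#' @param name variable code, e.g. `"BIO15"` or `"SOIL1"`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1 / 120,
                        nodata = -9999, name = "layer") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(nrow(values) >= 1, ncol(values) >= 1, cellsize > 0)
  if (any(is.infinite(values))) stop("raster values must be finite or NA")
  structure(
    list(nrows = nrow(values), ncols = ncol(values),
         xll = xll, yll = yll, cellsize = cellsize,
         nodata = nodata, values = values, name = name),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid '%s'> %d x %d cells, cellsize %g, origin (%g, %g), %d NA\n",
              x$name, x$nrows, x$ncols, x$cellsize, x$xll, x$yll,
              sum(is.na(x$values))))
  invisible(x)
}

grid_header_equal <- function(a, b) {
  isTRUE(all.equal(c(a$nrows, a$ncols, a$xll, a$yll, a$cellsize),
                   c(b$nrows, b$ncols, b$xll, b$yll, b$cellsize),
                   tolerance = 1e-9))
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line header (`NCOLS`, `NROWS`, `XLLCORNER`, `YLLCORNER`,
#' `CELLSIZE`, `NODATA_VALUE`, case-insensitive) followed by the value
#' block. Cells equal to the nodata sentinel become `NA`.
#'
#' @param path file path.
#' @param name variable code to attach; defaults to the file base name.
#' @return A [raster_grid].
#' @export
read_ascii_grid <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) {
    stop(sprintf("'%s': too short for an ESRI ASCII grid (%d lines)",
                 path, length(lines)))
  }
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("'%s' line %d: expected 'KEY value', got '%s'",
                   path, i, lines[i]))
    }
    hdr[[toupper(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE",
            "NODATA_VALUE")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0) {
    stop(sprintf("'%s': header missing %s", path,
                 paste(miss, collapse = ", ")))
  }
  if (any(vapply(hdr[need], is.na, TRUE))) {
    stop(sprintf("'%s': non-numeric header value", path))
  }
  nr <- as.integer(hdr$NROWS); nc <- as.integer(hdr$NCOLS)
  vals <- suppressWarnings(as.numeric(scan(
    text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE,
    what = double()
  )))
  if (length(vals) != nr * nc) {
    stop(sprintf("'%s' line 7+: expected %d values (%d x %d), found %d",
                 path, nr * nc, nr, nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$NODATA_VALUE] <- NA_real_
  raster_grid(m, xll = hdr$XLLCORNER, yll = hdr$YLLCORNER,
              cellsize = hdr$CELLSIZE, nodata = hdr$NODATA_VALUE,
              name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [raster_grid].
#' @param path output file path.
#' @param digits decimal places written for cell values (integer grids such
#'   as class maps round-trip exactly at any setting).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 6) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    sprintf("NCOLS %d", grid$ncols),
    sprintf("NROWS %d", grid$nrows),
    sprintf("XLLCORNER %.10g", grid$xll),
    sprintf("YLLCORNER %.10g", grid$yll),
    sprintf("CELLSIZE %.10g", grid$cellsize),
    sprintf("NODATA_VALUE %.10g", grid$nodata)
  )
  body <- apply(v, 1, function(row) {
    paste(formatC(row, format = "f", digits = digits), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Assemble aligned raster layers into a scenario stack
#'
#' A scenario stack is a named collection of co-registered layers under one
#' scenario label (e.g. `"current"`, `"2050s-SSP585"`). All layers must share
#' header geometry and mask (a cell is `NA` in every layer or in none).
#'
#' @param layers named list of [raster_grid] objects.
#' @param label scenario label.
#' @return An object of class `scenario_stack`.
#' @export
scenario_stack <- function(layers, label = "current") {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- vapply(layers, function(l) l$name, "")
  }
  if (anyDuplicated(names(layers))) stop("duplicate layer names in stack")
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!inherits(l, "raster_grid")) stop("all layers must be raster_grid")
    if (!grid_header_equal(ref, l)) {
      stop(sprintf("layer '%s' is not aligned with '%s' (header mismatch)",
                   nm, ref$name))
    }
    l$name <- nm
    layers[[nm]] <- l
  }
  ref_mask <- is.na(ref$values)
  for (nm in names(layers)) {
    if (!identical(is.na(layers[[nm]]$values), ref_mask)) {
      stop(sprintf("layer '%s': mask differs from '%s'", nm, ref$name))
    }
  }
  structure(list(label = label, layers = layers), class = "scenario_stack")
}

#' @export
print.scenario_stack <- function(x, ...) {
  cat(sprintf("<scenario_stack '%s'> %d layers: %s\n", x$label,
              length(x$layers),
              paste(utils::head(names(x$layers), 8), collapse = ", ")))
  invisible(x)
}

#' Flatten a stack to a cells-by-layers matrix
#'
#' Returns one row per non-masked cell, one column per layer, plus the
#' row/column indices of each cell as an attribute. Cell order is row-major
#' from the north-west corner, matching the file layout.
#'
#' @param stack a [scenario_stack].
#' @return numeric matrix with attribute `cells` (two-column matrix of
#'   row/col indices into the grid).
#' @export
stack_matrix <- function(stack) {
  stopifnot(inherits(stack, "scenario_stack"))
  ref <- stack$layers[[1]]
  idx <- arrayInd(which(!is.na(ref$values)), dim(ref$values))
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  m <- vapply(stack$layers, function(l) {
    l$values[cbind(idx[, 1], idx[, 2])]
  }, numeric(nrow(idx)))
  m <- matrix(m, nrow = nrow(idx),
              dimnames = list(NULL, names(stack$layers)))
  attr(m, "cells") <- idx
  m
}

#' Number of usable (non-masked) cells in a stack
#' @param stack a [scenario_stack].
#' @return integer count.
#' @export
n_cells <- function(stack) {
  sum(!is.na(stack$layers[[1]]$values))
}

# map lon/lat to 1-based (row, col); half-open cells [x, x+cs) x [y, y+cs),
# so points on the extreme top/right extent fall outside
locate_cells <- function(grid, lon, lat) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row_from_s <- floor((lat - grid$yll) / grid$cellsize) + 1
  row <- grid$nrows - row_from_s + 1
  inside <- col >= 1 & col <= grid$ncols & row >= 1 & row <= grid$nrows
  cbind(row = ifelse(inside, row, NA_integer_),
        col = ifelse(inside, col, NA_integer_))
}

#' Read a stack from a manifest file
#'
#' The manifest is a CSV with columns `variable,path` mapping layer codes to
#' ESRI ASCII grid files; relative paths are resolved against the manifest's
#' directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @param label scenario label for the assembled stack.
#' @return A [scenario_stack].
#' @export
read_stack <- function(manifest_path, label = "current") {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("variable", "path") %in% names(man))) {
    stop("stack manifest needs columns 'variable' and 'path'")
  }
  base <- dirname(manifest_path)
  layers <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p)) {
      stop(sprintf("stack '%s': layer '%s' file not found ('%s')",
                   label, man$variable[i], man$path[i]))
    }
    read_ascii_grid(p, name = man$variable[i])
  })
  names(layers) <- man$variable
  scenario_stack(layers, label = label)
}

#' Write a stack as ESRI ASCII grids plus a manifest
#'
#' @param stack a [scenario_stack].
#' @param dir output directory (created if needed).
#' @param digits decimal places for cell values.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_stack <- function(stack, dir, digits = 6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stack$layers), function(nm) {
    f <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], f, digits = digits)
    paste0(nm, ".asc")
  }, "")
  man <- data.frame(variable = names(stack$layers), path = unname(paths))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}
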