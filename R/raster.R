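#' Create a georeferenced raster grid
#'
#' Lightweight in-memory raster: a numeric matrix whose first row is the
#' *northernmost* row of cells, together with the cell size and the
#' coordinates of the lower-left corner of the grid. `NA` cells are NoData
#' and are treated as masked (outside the study extent) by every operation
#' in the package.
#'
#' @param values numeric matrix of cell values (row 1 = top of the map);
#'   `NA` marks NoData cells.
#' @param cell_size edge length of a (square) cell, in the projected
#'   distance units of the coordinate system (typically metres).
#' @param xll,yll x and y coordinate of the lower-left corner.
#' @return an object of class `lg_raster`.
#' @export
lg_raster <- function(values, cell_size = 1, xll = 0, yll = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have positive dimensions", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "lg_raster")
}

#' @export
print.lg_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<lg_raster> %d x %d cells, cell size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$xll, x$yll))
  cat(sprintf("  values: [%g, %g], %d NoData cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.lg_raster <- function(x) dim(x$values)

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol
}

#' Cell-centre coordinates of a raster
#'
#' @param raster an [lg_raster].
#' @param rows,cols integer cell indices (1-based, row 1 = top).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_xy <- function(raster, rows, cols) {
  nr <- nrow(raster$values)
  data.frame(
    x = raster$xll + (cols - 0.5) * raster$cell_size,
    y = raster$yll + (nr - rows + 0.5) * raster$cell_size)
}

#' Circular moving-window (focal) mean
#'
#' Replaces every non-masked cell by the mean of the non-masked cells whose
#' centres fall within `radius` of its centre (the cell itself included).
#' This emulates the moving-window percent-cover summaries commonly used to
#' build landscape predictor layers (e.g. mean sagebrush or canopy cover
#' within a 6.44 km window). Masked cells stay masked and do not contribute
#' to any window.
#'
#' @param raster an [lg_raster].
#' @param radius window radius in distance units; must be at least one cell.
#' @return an [lg_raster] on the same grid.
#' @export
focal_mean <- function(raster, radius) {
  stopifnot(inherits(raster, "lg_raster"))
  if (radius < raster$cell_size)
    stop("radius must be at least one cell size", call. = FALSE)
  r_cells <- radius / raster$cell_size
  k <- floor(r_cells)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  off <- off[off$dr^2 + off$dc^2 <= r_cells^2 + 1e-12, , drop = FALSE]
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  vz <- ifelse(is.na(v), 0, v)
  ok <- !is.na(v)
  for (i in seq_len(nrow(off))) {
    dr <- off$dr[i]; dc <- off$dc[i]
    sr <- max(1, 1 - dr):min(nr, nr - dr)   # destination rows
    sc <- max(1, 1 - dc):min(nc, nc - dc)
    num[sr, sc] <- num[sr, sc] + vz[sr + dr, sc + dc]
    den[sr, sc] <- den[sr, sc] + ok[sr + dr, sc + dc]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!ok] <- NA_real_
  res <- raster; res$values <- out
  res
}

#' Bilinear resampling to a coarser resolution
#'
#' Resamples a raster to a larger target cell size by bilinear interpolation
#' at the new cell centres (the standard preparation step before building
#' resistance surfaces at the analysis resolution, e.g. 1.2 km). A target
#' cell whose four surrounding source-cell centres include a NoData cell, or
#' which falls outside the source cell-centre hull, is NoData.
#'
#' @param raster an [lg_raster].
#' @param target_cell new cell size; must be `>=` the source cell size
#'   (upsampling is not supported).
#' @return an [lg_raster] at the target resolution covering the same extent.
#' @export
resample_bilinear <- function(raster, target_cell) {
  stopifnot(inherits(raster, "lg_raster"))
  if (target_cell < raster$cell_size)
    stop("target_cell must be >= source cell size (no upsampling)",
         call. = FALSE)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  w <- nc * raster$cell_size
  h <- nr * raster$cell_size
  nc2 <- max(1L, floor(w / target_cell))
  nr2 <- max(1L, floor(h / target_cell))
  out <- matrix(NA_real_, nr2, nc2)
  # fractional source coordinates: source cell r has its centre at fr = r
  # (rows counted from the top), source cell c at fc = c
  lower_index <- function(f, n) {
    lo <- floor(f); w <- f - lo
    if (lo >= n && f <= n + 1e-9) { lo <- n - 1; w <- 1 }
    list(lo = as.integer(lo), w = w)
  }
  for (i in seq_len(nr2)) {
    fr <- (i - 0.5) * target_cell / raster$cell_size + 0.5
    ri <- lower_index(fr, nr)
    if (ri$lo < 1L || ri$lo + 1L > nr) next
    for (j in seq_len(nc2)) {
      fc <- (j - 0.5) * target_cell / raster$cell_size + 0.5
      ci <- lower_index(fc, nc)
      if (ci$lo < 1L || ci$lo + 1L > nc) next
      q <- v[c(ri$lo, ri$lo + 1L), c(ci$lo, ci$lo + 1L)]
      if (anyNA(q)) next
      wr <- ri$w; wc <- ci$w
      out[i, j] <- (1 - wr) * ((1 - wc) * q[1, 1] + wc * q[1, 2]) +
        wr * ((1 - wc) * q[2, 1] + wc * q[2, 2])
    }
  }
  lg_raster(out, cell_size = target_cell, xll = raster$xll,
            yll = raster$yll + h - nr2 * target_cell)
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text grid exchange format with a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`). Round-tripping
#' preserves the grid, mask, cell size and origin.
#'
#' @param path file path.
#' @param raster an [lg_raster] (for writing).
#' @param nodata value written for NoData cells.
#' @return `read_ascii_grid` returns an [lg_raster]; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$nrows * hdr$ncols)
    stop("ASCII grid body has wrong cell count in ", path, call. = FALSE)
  v <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  v[v == nodata] <- NA_real_
  lg_raster(v, cell_size = hdr$cellsize, xll = hdr$xllcorner,
            yll = hdr$yllcorner)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "lg_raster"))
  v <- raster$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$xll),
    sprintf("yllcorner %.10g", raster$yll),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  rows <- apply(v, 1L, function(r) paste(format(r, trim = TRUE,
                                                digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
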