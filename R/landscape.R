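#' Categorical landscape raster
#'
#' A gridded landscape of the four categories in [landscape_categories()],
#' indexed row-major from the lower-left corner; `cells[row, col]` holds an
#' integer code 1--4 with row 1 the southernmost row. Positions and the
#' raster share one projected metric coordinate system (y increases north).
#'
#' @param cells Integer matrix of category codes in 1..4 (`n_rows` x
#'   `n_cols`).
#' @param origin Numeric length-2, (x, y) of the lower-left corner in metres.
#' @param cell_size Cell edge length in metres (> 0).
#' @return An object of class `categorical_raster`.
#' @export
categorical_raster <- function(cells, origin = c(0, 0), cell_size = 0.7) {
  cells <- as.matrix(cells)
  if (nrow(cells) < 1L || ncol(cells) < 1L) stop("raster must be non-empty")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be positive")
  storage.mode(cells) <- "integer"
  if (anyNA(cells) || any(cells < 1L) || any(cells > 4L))
    stop("cells must hold category codes 1..4 with no NoData")
  structure(list(cells = cells, origin = as.numeric(origin),
                 cell_size = cell_size,
                 n_rows = nrow(cells), n_cols = ncol(cells),
                 categories = landscape_categories()),
            class = "categorical_raster")
}

#' @export
print.categorical_raster <- function(x, ...) {
  fr <- tabulate(x$cells, 4L) / length(x$cells)
  cat(sprintf("<categorical_raster> %d x %d cells @ %.3g m\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$origin[1], x$origin[1] + x$n_cols * x$cell_size,
              x$origin[2], x$origin[2] + x$n_rows * x$cell_size))
  cat("  fractions:", paste(sprintf("%s %.2f", x$categories, fr),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Raster extent
#' @param raster A [categorical_raster()].
#' @return Named numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(raster) {
  c(xmin = raster$origin[1],
    xmax = raster$origin[1] + raster$n_cols * raster$cell_size,
    ymin = raster$origin[2],
    ymax = raster$origin[2] + raster$n_rows * raster$cell_size)
}

#' Generate a synthetic categorical landscape
#'
#' Stands in for classified aerial imagery: the grid is tiled into square
#' blocks (patches) of `block_cells` cells on a side, each block is assigned
#' one category, and block counts follow the requested proportions exactly up
#' to rounding before a seeded shuffle places them. Optional straight
#' "road" strips of pavement can be overlaid to mimic the linear features of
#' an urban landscape. Deterministic given `seed`.
#'
#' @param n_cols,n_rows Grid dimensions (positive).
#' @param cell_size Cell edge in metres.
#' @param proportions Numeric length-4, requested category fractions in the
#'   order of [landscape_categories()]; must be nonnegative and sum to ~1.
#' @param block_cells Patch edge length in cells (default scales with grid).
#' @param road_strips Number of pavement strips to overlay (default 0).
#' @param origin Lower-left corner (metres).
#' @param seed Integer seed.
#' @return A [categorical_raster()].
#' @export
generate_synthetic_raster <- function(n_cols, n_rows, cell_size = 0.7,
                                      proportions = rep(0.25, 4),
                                      block_cells = NULL, road_strips = 0,
                                      origin = c(0, 0), seed = 1L) {
  if (n_cols < 1L || n_rows < 1L) stop("raster dimensions must be positive")
  if (length(proportions) != 4L || any(proportions < 0))
    stop("`proportions` must be 4 nonnegative numbers")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("`proportions` must sum to 1")
  if (is.null(block_cells))
    block_cells <- max(1L, floor(min(n_cols, n_rows) / 20))
  nbr <- ceiling(n_rows / block_cells)
  nbc <- ceiling(n_cols / block_cells)
  nb <- nbr * nbc
  # exact count allocation, remainder to the largest requested categories
  counts <- floor(proportions * nb)
  rem <- nb - sum(counts)
  if (rem > 0) {
    extra <- order(proportions * nb - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  cells <- with_seed(seed, {
    codes <- sample(rep.int(1:4, counts))
    block_grid <- matrix(codes, nbr, nbc)
    rows <- pmin.int(((seq_len(n_rows) - 1L) %/% block_cells) + 1L, nbr)
    cols <- pmin.int(((seq_len(n_cols) - 1L) %/% block_cells) + 1L, nbc)
    g <- block_grid[rows, cols, drop = FALSE]
    if (road_strips > 0) {
      width <- max(1L, round(3.5 / cell_size))  # ~3.5 m road width
      for (k in seq_len(road_strips)) {
        if (k %% 2L == 1L) {
          at <- sample.int(n_rows - width + 1L, 1L)
          g[at:(at + width - 1L), ] <- 2L
        } else {
          at <- sample.int(n_cols - width + 1L, 1L)
          g[, at:(at + width - 1L)] <- 2L
        }
      }
    }
    g
  })
  categorical_raster(cells, origin = origin, cell_size = cell_size)
}

#' Landscape category at a position
#'
#' Cells are half-open intervals `[x0 + i*h, x0 + (i+1)*h)` in both axes, so
#' a point on a shared interior edge belongs to the higher-index cell; the
#' outer maximum edge is outside the extent.
#'
#' @param raster A [categorical_raster()].
#' @param position Numeric length-2 (x, y) in metres, or an n x 2 matrix.
#' @return Category name(s) from [landscape_categories()].
#' @export
feature_at <- function(raster, position) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2L)
  col <- floor((pos[, 1L] - raster$origin[1]) / raster$cell_size) + 1L
  row <- floor((pos[, 2L] - raster$origin[2]) / raster$cell_size) + 1L
  bad <- col < 1L | col > raster$n_cols | row < 1L | row > raster$n_rows
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("position (%g, %g) lies outside the raster extent",
                 pos[i, 1L], pos[i, 2L]))
  }
  raster$categories[raster$cells[cbind(row, col)]]
}

#' One-hot design row for a landscape category
#'
#' Cell-means coding: one coefficient per category, fixed order
#' (tree, pavement, grass, building), so Phi(mu_beta[k]) is directly the
#' movement probability from feature k. No intercept.
#'
#' @param category Category name(s).
#' @return For one category, a named length-4 indicator vector; for several,
#'   a matrix with one row each.
#' @export
design_row <- function(category) {
  cats <- landscape_categories()
  idx <- match(category, cats)
  if (anyNA(idx))
    stop("unknown landscape category: ",
         paste(category[is.na(idx)], collapse = ", "))
  m <- diag(4L)[idx, , drop = FALSE]
  colnames(m) <- cats
  if (length(category) == 1L) m[1L, ] else m
}

#' Write a categorical raster as an ESRI ASCII grid
#'
#' Plain-text interchange format: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of integer codes from
#' the top (northernmost) row down.
#'
#' @param raster A [categorical_raster()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", raster$n_cols),
               sprintf("nrows %d", raster$n_rows),
               sprintf("xllcorner %.10g", raster$origin[1]),
               sprintf("yllcorner %.10g", raster$origin[2]),
               sprintf("cellsize %.10g", raster$cell_size),
               "NODATA_value -9999"), con)
  for (r in raster$n_rows:1)
    writeLines(paste(raster$cells[r, ], collapse = " "), con)
  invisible(path)
}

#' Read a categorical raster from an ESRI ASCII grid
#'
#' Codes must be 1--4 in the order of [landscape_categories()]; NoData cells
#' are rejected (synthetic landscapes are fully classified).
#'
#' @param path File path.
#' @return A [categorical_raster()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("missing ESRI ASCII header field: ", k)
  vals <- scan(text = lines[i:length(lines)], what = integer(), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match header dimensions")
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata) && any(vals == nodata))
    stop("raster contains NoData cells; fully classified input required")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[hdr$nrows:1, , drop = FALSE]   # file stores top row first
  categorical_raster(m, origin = c(hdr$xllcorner, hdr$yllcorner),
                     cell_size = hdr$cellsize)
}
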