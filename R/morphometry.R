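#' Per-cell morphometry: cell area, projection area, ramification index
#'
#' The ramification index RI = A_c / A_p contrasts the stained silhouette of
#' a microglial cell (cell area A_c) with the territory spanned by its most
#' prominent projections (projection area A_p, the area of the cell's convex
#' hull). A ramified resting cell has long thin processes, a large hull and
#' a small silhouette, hence a low RI; an activated amoeboid cell is nearly
#' convex and its RI approaches 1.
#'
#' Convention: a cell is a set of foreground pixels; A_c counts pixels times
#' the pixel area, and A_p is the convex hull of *all four corner points of
#' every foreground pixel square*. Because that hull contains the union of
#' the pixel squares, A_p >= A_c always holds and RI is guaranteed to lie in
#' (0, 1] — including for one-pixel-wide straight cells, whose corner hull
#' is still a full rectangle.
#'
#' @name morphometry
NULL

#' Cell area A_c in square micrometres
#'
#' @param px n x 2 matrix of 0-based `(x, y)` foreground pixel coordinates.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return Area in um^2: `nrow(px) * pixel_size_um^2`.
#' @export
cell_area <- function(px, pixel_size_um) {
  if (is.null(px) || nrow(px) == 0L) stop("empty pixel set")
  stopifnot(pixel_size_um > 0)
  nrow(px) * pixel_size_um^2
}

# unique corner points of the pixel squares [x, x+1] x [y, y+1]
pixel_corners <- function(px) {
  corners <- rbind(
    cbind(px[, 1],     px[, 2]),
    cbind(px[, 1] + 1, px[, 2]),
    cbind(px[, 1],     px[, 2] + 1),
    cbind(px[, 1] + 1, px[, 2] + 1)
  )
  unique(corners)
}

#' Projection area A_p in square micrometres
#'
#' Area of the convex hull of all corner points of the foreground pixel
#' squares (Andrew/Graham hull via [grDevices::chull()], area by the
#' shoelace formula), scaled by the squared pixel size.
#'
#' @inheritParams cell_area
#' @return Hull area in um^2; always `>=` [cell_area()].
#' @export
projection_area <- function(px, pixel_size_um) {
  if (is.null(px) || nrow(px) == 0L) stop("empty pixel set")
  stopifnot(pixel_size_um > 0)
  corners <- pixel_corners(px)
  h <- grDevices::chull(corners[, 1], corners[, 2])
  abs(shoelace_area(corners[h, , drop = FALSE])) * pixel_size_um^2
}

#' Ramification index RI = A_c / A_p
#'
#' @param A_c Cell area (um^2), `> 0`.
#' @param A_p Projection area (um^2), `>= A_c`.
#' @return RI in `(0, 1]`; values near 1 indicate an amoeboid (activated)
#'   morphology, low values a ramified (resting) one.
#' @export
ramification_index <- function(A_c, A_p) {
  if (!(A_c > 0)) stop("A_c must be positive")
  if (A_p < A_c * (1 - 1e-12)) {
    stop("internal consistency failure: A_p < A_c (hull must contain the cell)")
  }
  min(A_c / A_p, 1)
}

# morphometry of a raw pixel set; used both by the pipeline and as the
# ground-truth RI of synthetic cells
mask_morphometry <- function(px, pixel_size_um) {
  a_c <- cell_area(px, pixel_size_um)
  a_p <- projection_area(px, pixel_size_um)
  list(A_c = a_c, A_p = a_p, RI = ramification_index(a_c, a_p))
}

#' Sampling grid for random cell selection
#'
#' Cells are selected for morphometry by superimposing a rectangular grid
#' with uniform line spacing in x and y and keeping every cell that crosses
#' a grid line. Random phase (offset) makes the selection a random sample;
#' fixed offsets make it reproducible across reruns.
#'
#' @param spacing_px Distance between grid lines in pixels (`> 0`).
#' @param offset_x,offset_y Grid phase in `[0, spacing)`; `NULL` = draw
#'   uniformly at random when the grid is applied.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(spacing_px, offset_x = NULL, offset_y = NULL) {
  stopifnot(is.numeric(spacing_px), spacing_px > 0)
  chk <- function(o) is.null(o) || (o >= 0 && o < spacing_px)
  if (!chk(offset_x) || !chk(offset_y)) stop("offsets must lie in [0, spacing)")
  structure(list(spacing_px = spacing_px, offset_x = offset_x,
                 offset_y = offset_y),
            class = "grid_spec")
}

#' Select cells crossing grid lines
#'
#' A cell is selected iff its pixel set intersects any vertical line
#' `x = offset_x + k * spacing` or horizontal line
#' `y = offset_y + k * spacing`. The pixel square `[i, i+1) x [j, j+1)`
#' intersects the line `x = c` iff `i <= c < i + 1`, i.e. `floor(c) == i`.
#'
#' @param cells List of cells as returned by [detect_cells()].
#' @param grid A [grid_spec()]; missing offsets are drawn from the current
#'   RNG stream.
#' @param shape `c(height, width)` of the image in pixels.
#' @return List with `selected` (subset of `cells`), `index` (positions in
#'   the input list) and `offsets` (`c(x, y)` actually used).
#' @export
grid_sample_cells <- function(cells, grid, shape) {
  stopifnot(inherits(grid, "grid_spec"))
  ny <- shape[1]; nx <- shape[2]
  s <- grid$spacing_px
  ox <- if (is.null(grid$offset_x)) stats::runif(1, 0, s) else grid$offset_x
  oy <- if (is.null(grid$offset_y)) stats::runif(1, 0, s) else grid$offset_y
  xlines <- if (ox < nx) seq(ox, nx - 1e-12, by = s) else numeric(0)
  ylines <- if (oy < ny) seq(oy, ny - 1e-12, by = s) else numeric(0)
  xcols <- unique(floor(xlines))
  yrows <- unique(floor(ylines))
  hit <- vapply(cells, function(cell) {
    any(cell$px[, 1] %in% xcols) || any(cell$px[, 2] %in% yrows)
  }, logical(1))
  list(selected = cells[hit], index = which(hit), offsets = c(x = ox, y = oy))
}

#' Detect, grid-sample and measure cells in one image
#'
#' Full morphometry stage: binarize (Otsu within the ROI) unless a mask is
#' supplied, detect cells, drop cells touching the image border (truncated
#' silhouettes bias RI upward), select cells crossing the sampling grid, and
#' compute A_c, A_p and RI for each selected cell.
#'
#' @param img A [gray_image()], or a logical matrix already binarized.
#' @param roi A [roi_polygon()] or a logical ROI mask.
#' @param params A [detection_params()].
#' @param grid A [grid_spec()]; default spacing is image width / 8 with
#'   random phase.
#' @param pixel_size_um Pixel size; taken from `img` when it is a
#'   [gray_image()].
#' @param threshold A [threshold_spec()] used when `img` is a gray image.
#' @return List with `cells` (data frame: cell_id, centroid_x, centroid_y,
#'   area_um2, hull_area_um2, ri), `mean_ri`, `n_selected`, `n_detected`,
#'   `cutoff` (NA when a mask was supplied) and `grid_offsets`.
#' @export
analyze_cells <- function(img, roi, params = detection_params(),
                          grid = NULL, pixel_size_um = NULL,
                          threshold = threshold_spec()) {
  if (inherits(img, "gray_image")) {
    pixel_size_um <- img$pixel_size_um
    shape <- dim(img$pixels)
  } else {
    if (is.null(pixel_size_um)) stop("`pixel_size_um` required for mask input")
    shape <- dim(img)
  }
  roi_mask <- if (inherits(roi, "roi_polygon")) rasterize_roi(roi, shape) else roi
  cutoff <- NA_real_
  if (inherits(img, "gray_image")) {
    b <- binarize(img, threshold, roi_mask)
    mask <- b$mask
    cutoff <- b$cutoff
  } else {
    mask <- img
  }
  cells <- detect_cells(mask, roi_mask, params, pixel_size_um)
  # exclude cells touching the image border
  ny <- shape[1]; nx <- shape[2]
  interior <- vapply(cells, function(cell) {
    !(any(cell$px[, 1] == 0L) || any(cell$px[, 1] == nx - 1L) ||
      any(cell$px[, 2] == 0L) || any(cell$px[, 2] == ny - 1L))
  }, logical(1))
  cells <- cells[interior]
  if (is.null(grid)) grid <- grid_spec(nx / 8)
  sel <- grid_sample_cells(cells, grid, shape)
  recs <- lapply(seq_along(sel$selected), function(i) {
    cell <- sel$selected[[i]]
    m <- mask_morphometry(cell$px, pixel_size_um)
    data.frame(cell_id = i, centroid_x = cell$centroid[1],
               centroid_y = cell$centroid[2], area_um2 = m$A_c,
               hull_area_um2 = m$A_p, ri = m$RI)
  })
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(cell_id = integer(0), centroid_x = numeric(0),
               centroid_y = numeric(0), area_um2 = numeric(0),
               hull_area_um2 = numeric(0), ri = numeric(0))
  if (nrow(df) == 0L) warning("no cells selected by the sampling grid")
  rownames(df) <- NULL
  list(cells = df,
       mean_ri = if (nrow(df)) mean(df$ri) else NA_real_,
       n_selected = nrow(df), n_detected = length(cells),
       cutoff = cutoff, grid_offsets = sel$offsets)
}
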