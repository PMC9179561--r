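#' Label connected components of a binary mask
#'
#' Flood-fill labelling at 4- or 8-connectivity. 8-connectivity (the
#' default elsewhere in the package) keeps thin diagonal microglial
#' processes attached to their somata.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape: 0 = background, components
#'   numbered 1..k in discovery (column-major) order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  offs <- if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = rep(c(-1L, 0L, 1L), 3L), dc = rep(c(-1L, 0L, 1L), each = 3L))[-5L, ]
  }
  fg <- which(mask)
  k <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    k <- k + 1L
    lab[seed] <- k
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% ny + 1L
      cc <- (frontier - 1L) %/% ny + 1L
      nb <- integer(0)
      for (o in seq_len(nrow(offs))) {
        rr <- r + offs[o, 1L]; ccc <- cc + offs[o, 2L]
        ok <- rr >= 1L & rr <= ny & ccc >= 1L & ccc <= nx
        if (any(ok)) nb <- c(nb, (ccc[ok] - 1L) * ny + rr[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- k
      frontier <- nb
    }
  }
  lab
}

#' Detection parameters for component-based cell counting
#'
#' @param min_area_um2 Minimum component area in um^2 (rejects noise specks).
#' @param max_area_um2 Maximum component area (default unbounded).
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_area_um2 = 20, max_area_um2 = Inf,
                             connectivity = 8) {
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2)) {
    stop("need 0 < min_area_um2 < max_area_um2")
  }
  stopifnot(connectivity %in% c(4, 8))
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 connectivity = connectivity),
            class = "detection_params")
}

#' Detect cells as connected components inside an ROI
#'
#' Components of the positive mask are labelled at the configured
#' connectivity, filtered by physical area, and kept iff their centroid
#' falls inside the ROI mask. The centroid rule counts each cell exactly
#' once even when it straddles the ROI border, so adjacent ROIs never
#' double-count.
#'
#' @param mask Logical matrix of positive pixels.
#' @param roi_mask Logical matrix of the ROI (same shape).
#' @param params A [detection_params()].
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return List of cells; each cell is a list with `px` (n x 2 integer
#'   matrix of 0-based `(x, y)` pixel coordinates), `centroid` (`(x, y)` in
#'   pixel units, centre-of-mass of pixel centres), and `area_um2`.
#' @export
detect_cells <- function(mask, roi_mask, params = detection_params(),
                         pixel_size_um) {
  if (!identical(dim(mask), dim(roi_mask))) {
    stop("`mask` and `roi_mask` must have identical dimensions")
  }
  stopifnot(inherits(params, "detection_params"), pixel_size_um > 0)
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- label_components(mask, params$connectivity)
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  comp <- split(idx, lab[idx])
  pxa <- pixel_size_um^2
  out <- list()
  for (ci in seq_along(comp)) {
    lin <- comp[[ci]]
    a <- length(lin) * pxa
    if (a < params$min_area_um2 || a > params$max_area_um2) next
    x <- (lin - 1L) %/% ny          # 0-based column index = x
    y <- (lin - 1L) %% ny           # 0-based row index = y
    cx <- mean(x) + 0.5
    cy <- mean(y) + 0.5
    # centroid-in-ROI: the pixel containing the centroid must be in the ROI
    r <- floor(cy) + 1L; cc <- floor(cx) + 1L
    if (r < 1L || r > ny || cc < 1L || cc > nx || !roi_mask[r, cc]) next
    out[[length(out) + 1L]] <- list(
      px = cbind(x = as.integer(x), y = as.integer(y)),
      centroid = c(x = cx, y = cy),
      area_um2 = a
    )
  }
  out
}

#' Cell density in cells per square millimetre
#'
#' @param count Number of cells counted inside the ROI.
#' @param roi_area Area of the ROI in mm^2 (strictly positive).
#' @return Density in cells/mm^2.
#' @export
cells_per_mm2 <- function(count, roi_area) {
  if (!is.numeric(roi_area) || roi_area <= 0) {
    stop("`roi_area` must be positive (mm^2)")
  }
  count / roi_area
}
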