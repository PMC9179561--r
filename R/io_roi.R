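#' Grayscale micrograph with physical pixel size
#'
#' Container for a single-channel 8-bit-convention intensity raster together
#' with the physical edge length of one pixel. All downstream quantification
#' (densitometry, cell detection, morphometry) consumes this object.
#'
#' Coordinate convention, used throughout the package: pixel `(0, 0)` sits at
#' the top-left corner, x runs rightward (matrix columns), y runs downward
#' (matrix rows), and the centre of pixel `(x, y)` is at `(x + 0.5, y + 0.5)`.
#' `pixels[j, i]` holds pixel `(x = i - 1, y = j - 1)`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]` (rows = y,
#'   columns = x).
#' @param pixel_size_um Physical edge length of one pixel in micrometres
#'   (must be `> 0`).
#' @param name Free-text identifier carried through reports.
#' @return An object of class `gray_image` with elements `pixels`,
#'   `pixel_size_um` and `name`.
#' @export
gray_image <- function(pixels, pixel_size_um, name = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must contain at least one pixel")
  }
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie within [0, 255] and contain no NA")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number")
  }
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         name = as.character(name)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %s: %d x %d px, %.4g um/px\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Convert an RGB raster to grayscale intensities
#'
#' Applies the standard Rec. 601 luminance transform
#' `round(0.299 R + 0.587 G + 0.114 B)`, or the unweighted channel mean,
#' clipped to `[0, 255]`. DAB-positive signal (brown deposit) maps to dark
#' values under either transform.
#'
#' @param rgb Numeric array `height x width x 3` with values in `[0, 255]`.
#' @param method `"luminance"` (default) or `"mean"`.
#' @return Numeric matrix of grayscale intensities in `[0, 255]`.
#' @export
rgb_to_gray <- function(rgb, method = c("luminance", "mean")) {
  method <- match.arg(method)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("`rgb` must be a height x width x 3 array")
  }
  g <- if (method == "luminance") {
    0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  } else {
    (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  }
  g <- pmin(pmax(round(g), 0), 255)
  dim(g) <- dim(rgb)[1:2]
  g
}

#' Read a TIFF or PNG micrograph
#'
#' Reads 8- or 16-bit, single- or 3-channel rasters. 16-bit inputs are
#' rescaled linearly by the dtype maximum (not the image maximum, so constant
#' illumination stays comparable across sections); 3-channel inputs are
#' converted with [rgb_to_gray()]. Any pixel-size metadata in the file is
#' ignored: the physical pixel size is always the explicit argument.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um Physical pixel edge length in micrometres.
#' @param name Identifier; defaults to the file name.
#' @param grayscale Channel-mixing method for RGB inputs, see [rgb_to_gray()].
#' @return A [gray_image()].
#' @export
read_image <- function(path, pixel_size_um, name = basename(path),
                       grayscale = c("luminance", "mean")) {
  grayscale <- match.arg(grayscale)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (use TIFF or PNG)")
  )
  # both readers normalise to [0,1] regardless of bit depth; x/255 for 8-bit,
  # x/65535 for 16-bit, so scaling by 255 is exactly the dtype-max rescale
  raw <- raw * 255
  nd <- length(dim(raw))
  px <- if (nd == 2L) {
    raw
  } else if (dim(raw)[3] == 1L) {
    raw[, , 1]
  } else if (dim(raw)[3] %in% c(3L, 4L)) {
    rgb_to_gray(raw[, , 1:3], method = grayscale)
  } else {
    stop("unsupported channel count: ", dim(raw)[3])
  }
  gray_image(px, pixel_size_um, name = name)
}

#' Region-of-interest polygon in pixel coordinates
#'
#' A simple (non-self-intersecting), implicitly closed polygon outlining the
#' evaluation region on a micrograph — e.g. the medial corpus callosum,
#' medial retrosplenial cortex, or hippocampus. Anatomical placement is the
#' user's responsibility; the polygon is taken as given.
#'
#' @param vertices Numeric matrix (or two-column data frame) of at least 3
#'   `(x, y)` vertices in pixel coordinates, in drawing order.
#' @param label Region label: one of `"corpus_callosum"`, `"cortex"`,
#'   `"hippocampus"`, `"custom"`.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices,
                        label = c("custom", "corpus_callosum", "cortex",
                                  "hippocampus")) {
  label <- match.arg(label)
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L || !is.numeric(v) || anyNA(v)) {
    stop("`vertices` must be a numeric matrix of >= 3 (x, y) rows")
  }
  if (abs(shoelace_area(v)) < .Machine$double.eps) {
    stop("degenerate polygon: enclosed area is zero")
  }
  if (is_self_intersecting(v)) {
    stop("polygon must be simple (non-self-intersecting)")
  }
  colnames(v) <- c("x", "y")
  structure(list(vertices = v, label = label), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> %s: %d vertices, %.1f px^2\n",
              x$label, nrow(x$vertices), abs(shoelace_area(x$vertices))))
  invisible(x)
}

# signed shoelace area of an (x, y) vertex matrix, px^2
shoelace_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1L)
  sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2]) / 2
}

# proper-crossing test between non-adjacent edges; shared endpoints allowed
is_self_intersecting <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross2(q[1], q[2], q[3], q[4], p[1], p[2])
      d2 <- cross2(q[1], q[2], q[3], q[4], p[3], p[4])
      d3 <- cross2(p[1], p[2], p[3], p[4], q[1], q[2])
      d4 <- cross2(p[1], p[2], p[3], p[4], q[3], q[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its centre `(i + 0.5, j + 0.5)` lies
#' inside the polygon (even-odd rule); centres lying exactly on a polygon
#' edge are included. Scanline implementation, deterministic.
#'
#' @param roi A [roi_polygon()].
#' @param shape Integer vector `c(height, width)` of the target image, or a
#'   [gray_image()] whose shape is used.
#' @return Logical matrix of the given shape (`TRUE` = inside).
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi_polygon"))
  if (inherits(shape, "gray_image")) shape <- dim(shape$pixels)
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  v <- roi$vertices
  n <- nrow(v)
  i2 <- c(2:n, 1L)
  x1 <- v[, 1]; y1 <- v[, 2]; x2 <- v[i2, 1]; y2 <- v[i2, 2]
  mask <- matrix(FALSE, ny, nx)
  xc <- seq_len(nx) - 0.5
  for (j in seq_len(ny)) {
    y0 <- j - 0.5
    cr <- (y1 > y0) != (y2 > y0)
    inside <- rep(FALSE, nx)
    if (any(cr)) {
      xi <- x1[cr] + (y0 - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr])
      cnt <- colSums(outer(xi, xc, ">"))
      inside <- (cnt %% 2L) == 1L
      inside <- inside | colSums(outer(xi, xc, "==")) > 0
    }
    hor <- (y1 == y0) & (y2 == y0)
    if (any(hor)) {
      for (k in which(hor)) {
        inside <- inside | (xc >= min(x1[k], x2[k]) & xc <= max(x1[k], x2[k]))
      }
    }
    mask[j, ] <- inside
  }
  mask
}

#' Physical area of an ROI polygon in square millimetres
#'
#' Shoelace polygon area in px^2 scaled by the squared pixel size; the
#' denominator of the cells-per-mm^2 density read-out. Invariant under vertex
#' order reversal and cyclic rotation.
#'
#' @param roi A [roi_polygon()].
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return Area in mm^2 (strictly positive).
#' @export
roi_area_mm2 <- function(roi, pixel_size_um) {
  stopifnot(inherits(roi, "roi_polygon"), pixel_size_um > 0)
  abs(shoelace_area(roi$vertices)) * pixel_size_um^2 * 1e-6
}

#' Read / write ROI polygons as JSON
#'
#' The on-disk format is
#' `{"label": str, "pixel_size_um": num, "vertices": [[x, y], ...]}`.
#'
#' @param path JSON file path.
#' @return `read_roi_json()`: a list with elements `roi` ([roi_polygon()])
#'   and `pixel_size_um` (may be `NULL` when absent from the file).
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$vertices)) stop("ROI JSON lacks a `vertices` field")
  lab <- if (is.null(obj$label)) "custom" else obj$label
  v <- obj$vertices
  if (!is.matrix(v)) v <- do.call(rbind, lapply(v, unlist))
  list(roi = roi_polygon(v, label = lab), pixel_size_um = obj$pixel_size_um)
}

#' @rdname read_roi_json
#' @param roi A [roi_polygon()].
#' @param pixel_size_um Optional pixel size stored alongside the polygon.
#' @export
write_roi_json <- function(roi, path, pixel_size_um = NULL) {
  stopifnot(inherits(roi, "roi_polygon"))
  obj <- list(label = roi$label, pixel_size_um = pixel_size_um,
              vertices = unname(apply(roi$vertices, 1L, function(r) c(r[1], r[2]),
                                      simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param img A [gray_image()].
#' @param path Output PNG path.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
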