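#' Threshold specification for binary conversion
#'
#' The densitometric read-out classifies every pixel as positive (stained) or
#' negative by comparison against an intensity cutoff. DAB-positive signal is
#' dark after grayscale conversion, hence the default polarity
#' `"positive-below"`.
#'
#' Comparisons are strict (`<` / `>`): pixels equal to the cutoff go to
#' background, which makes thresholding bit-exactly reproducible.
#'
#' @param mode `"otsu"` (cutoff computed from the ROI histogram by Otsu's
#'   between-class variance criterion) or `"fixed"` (explicit cutoff).
#' @param value Intensity cutoff in `[0, 255]`; required for `mode = "fixed"`.
#' @param polarity `"positive-below"` or `"positive-above"`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(mode = c("otsu", "fixed"), value = NULL,
                           polarity = c("positive-below", "positive-above")) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  if (mode == "fixed") {
    if (is.null(value) || !is.numeric(value) || length(value) != 1L ||
        value < 0 || value > 255) {
      stop("fixed mode requires a single cutoff `value` in [0, 255]")
    }
  }
  structure(list(mode = mode, value = value, polarity = polarity),
            class = "threshold_spec")
}

#' Otsu cutoff on an intensity sample
#'
#' Returns the cutoff `c` in `1..255` maximising the between-class variance
#' of the two classes `{x < c}` and `{x >= c}` over the integer histogram of
#' `values` (ties broken toward the smallest cutoff). Intensities are binned
#' by rounding to integers 0..255.
#'
#' @param values Numeric vector of intensities in `[0, 255]`.
#' @return Integer cutoff in `1..255`.
#' @export
otsu_cutoff <- function(values) {
  otsu_cutoff_hist(tabulate(as.integer(round(values)) + 1L, nbins = 256L))
}

# Otsu on a 256-bin integer histogram (bin k = intensity k - 1)
otsu_cutoff_hist <- function(h) {
  if (sum(h > 0L) < 2L) {
    stop("degenerate histogram: Otsu needs at least two distinct intensities")
  }
  n <- sum(h)
  lev <- 0:255
  csum <- cumsum(h)            # csum[k] = #{x <= k-1} = #{x < k}
  cmom <- cumsum(h * lev)
  w0 <- csum[1:255] / n        # class {x < c}, c = 1..255
  w1 <- 1 - w0
  mu0 <- ifelse(csum[1:255] > 0, cmom[1:255] / csum[1:255], 0)
  mu1 <- ifelse(csum[1:255] < n, (cmom[256] - cmom[1:255]) / (n - csum[1:255]), 0)
  sb <- w0 * w1 * (mu0 - mu1)^2
  which.max(sb)                # cutoff c; which.max takes the first maximum
}

#' Binarize an image against a threshold
#'
#' Fixed mode compares each pixel with the given cutoff; Otsu mode first
#' computes the cutoff from the histogram of the pixels inside `roi_mask`
#' (or the whole image when no ROI is given), so background outside the
#' evaluation region cannot bias it.
#'
#' @param img A [gray_image()].
#' @param spec A [threshold_spec()].
#' @param roi_mask Optional logical matrix restricting the Otsu histogram.
#' @return A list with `mask` (logical matrix, `TRUE` = positive) and
#'   `cutoff` (the cutoff actually applied).
#' @export
binarize <- function(img, spec = threshold_spec(), roi_mask = NULL) {
  stopifnot(inherits(img, "gray_image"), inherits(spec, "threshold_spec"))
  px <- img$pixels
  cutoff <- if (spec$mode == "fixed") {
    spec$value
  } else {
    vals <- if (is.null(roi_mask)) px else px[roi_mask]
    otsu_cutoff(vals)
  }
  mask <- if (spec$polarity == "positive-below") px < cutoff else px > cutoff
  list(mask = mask, cutoff = cutoff)
}

#' Percent positive area within an ROI
#'
#' `100 * |positive AND roi| / |roi|` — the densitometric "staining
#' intensity" expressed as % area of the evaluation region.
#'
#' @param mask Logical matrix of positive pixels.
#' @param roi_mask Logical matrix of the ROI (same shape, >= 1 `TRUE` pixel).
#' @return Percentage in `[0, 100]`.
#' @export
percent_area <- function(mask, roi_mask) {
  if (!identical(dim(mask), dim(roi_mask))) {
    stop("`mask` and `roi_mask` must have identical dimensions")
  }
  n_roi <- sum(roi_mask)
  if (n_roi < 1L) stop("ROI mask is empty")
  100 * sum(mask & roi_mask) / n_roi
}

#' One Otsu cutoff from the pooled ROI histograms of several images
#'
#' Pools the ROI-restricted intensity histograms of a set of images acquired
#' under constant illumination and computes a single Otsu cutoff from the
#' pooled histogram. A shared cutoff mirrors the single-threshold workflow
#' of comparably illuminated sections and is robust where a per-image
#' histogram has too few positive pixels for a reliable bimodal split
#' (Otsu's criterion degrades at extreme class imbalance, e.g. weakly
#' stained control sections).
#'
#' @param images List of [gray_image()] objects.
#' @param roi_masks List of logical ROI masks, parallel to `images`.
#' @return Integer cutoff in `1..255`.
#' @export
pooled_otsu_cutoff <- function(images, roi_masks) {
  stopifnot(length(images) == length(roi_masks), length(images) >= 1L)
  h <- rep(0L, 256L)
  for (i in seq_along(images)) {
    vals <- images[[i]]$pixels[roi_masks[[i]]]
    h <- h + tabulate(as.integer(round(vals)) + 1L, nbins = 256L)
  }
  otsu_cutoff_hist(h)
}
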