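#' Quantify one scene with all three read-outs
#'
#' Runs the densitometry (ROI-restricted Otsu by default), cell counting and
#' morphometry stages on a single image/ROI pair.
#'
#' @param img A [gray_image()].
#' @param roi A [roi_polygon()].
#' @param threshold A [threshold_spec()].
#' @param detection A [detection_params()].
#' @param grid A [grid_spec()] or `NULL` for the default (width / 8, random
#'   phase from the current RNG stream).
#' @return List with `percent_area`, `cutoff`, `count`, `roi_area_mm2`,
#'   `cells_per_mm2`, `mean_ri`, `n_cells_measured` and the per-cell
#'   morphometry data frame `cells`.
#' @export
quantify_scene <- function(img, roi, threshold = threshold_spec(),
                           detection = detection_params(), grid = NULL) {
  stopifnot(inherits(img, "gray_image"), inherits(roi, "roi_polygon"))
  shape <- dim(img$pixels)
  roi_mask <- rasterize_roi(roi, shape)
  b <- binarize(img, threshold, roi_mask)
  pct <- percent_area(b$mask, roi_mask)
  cells <- detect_cells(b$mask, roi_mask, detection, img$pixel_size_um)
  area <- roi_area_mm2(roi, img$pixel_size_um)
  dens <- cells_per_mm2(length(cells), area)
  morph <- analyze_cells(b$mask, roi_mask, detection, grid,
                         pixel_size_um = img$pixel_size_um)
  list(percent_area = pct, cutoff = b$cutoff, count = length(cells),
       roi_area_mm2 = area, cells_per_mm2 = dens, mean_ri = morph$mean_ri,
       n_cells_measured = morph$n_selected, cells = morph$cells)
}

#' Run the full analysis pipeline over a synthetic cohort
#'
#' Orchestrates simulate -> (densitometry, counting, morphometry) -> group
#' statistics. Every scene of the cohort is quantified, per-animal values
#' are assembled per metric, and each metric is tested with
#' [run_group_analysis()] (Grubbs' screening applies to `percent_area`
#' only). When ground truth is present a recovery table (seeded vs.
#' recovered, relative error) is included.
#'
#' @param cohort A generated cohort from [generate_cohort()], or a
#'   [cohort_spec()] (which is generated first).
#' @param control Label of the control group (default the first group).
#' @param threshold,detection,grid Stage parameters, see [quantify_scene()].
#' @param threshold_scope `"cohort"` (default): when `threshold` is in Otsu
#'   mode, one cutoff is computed from the pooled ROI histograms of all
#'   scenes ([pooled_otsu_cutoff()]) and applied to every scene — the
#'   automated analogue of reusing one threshold across constant-illumination
#'   sections. `"per_image"`: each scene gets its own ROI-restricted Otsu
#'   cutoff.
#' @param seed Seed for the grid-phase RNG stream.
#' @return List with `values` (data frame: group, animal, metric, value),
#'   `stats` (list of `test_result` per metric), `recovery` (data frame) and
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, control = NULL,
                         threshold = threshold_spec(),
                         threshold_scope = c("cohort", "per_image"),
                         detection = detection_params(), grid = NULL,
                         seed = 1L) {
  threshold_scope <- match.arg(threshold_scope)
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  scenes <- cohort$scenes
  if (is.null(control)) control <- scenes[[1]]$group
  if (threshold_scope == "cohort" && threshold$mode == "otsu" &&
      length(scenes)) {
    masks <- lapply(scenes, function(sc)
      rasterize_roi(sc$roi, dim(sc$image$pixels)))
    cut <- pooled_otsu_cutoff(lapply(scenes, `[[`, "image"), masks)
    threshold <- threshold_spec("fixed", value = cut,
                                polarity = threshold$polarity)
  }
  rows <- list()
  with_preserved_seed(seed, {
    for (sc in scenes) {
      q <- quantify_scene(sc$image, sc$roi, threshold, detection, grid)
      rows[[length(rows) + 1L]] <- data.frame(
        group = sc$group, animal = sc$animal, name = sc$image$name,
        percent_area = q$percent_area, cutoff = q$cutoff, count = q$count,
        roi_area_mm2 = q$roi_area_mm2, cells_per_mm2 = q$cells_per_mm2,
        mean_ri = q$mean_ri, n_cells_measured = q$n_cells_measured)
    }
  })
  per_scene <- do.call(rbind, rows)
  values <- rbind(
    data.frame(group = per_scene$group, animal = per_scene$animal,
               metric = "density", value = per_scene$cells_per_mm2),
    data.frame(group = per_scene$group, animal = per_scene$animal,
               metric = "percent_area", value = per_scene$percent_area),
    data.frame(group = per_scene$group, animal = per_scene$animal,
               metric = "mean_ri", value = per_scene$mean_ri))
  n_groups <- length(unique(per_scene$group))
  stats_list <- list()
  if (n_groups >= 2L) {
    for (m in c("density", "percent_area", "mean_ri")) {
      d <- values[values$metric == m, c("group", "value")]
      d <- d[is.finite(d$value), , drop = FALSE]
      stats_list[[m]] <- run_group_analysis(d, m, control)
    }
  }
  recovery <- NULL
  if (!is.null(cohort$manifest)) {
    man <- cohort$manifest
    rec_of <- function(metric, seeded, recovered) data.frame(
      metric = metric, seeded = mean(seeded), recovered = mean(recovered),
      relative_error = abs(mean(recovered) - mean(seeded)) /
        max(abs(mean(seeded)), .Machine$double.eps))
    recovery <- rbind(
      rec_of("density", man$true_density, per_scene$cells_per_mm2),
      rec_of("percent_area", man$true_pct, per_scene$percent_area),
      rec_of("mean_ri", man$true_mean_ri, per_scene$mean_ri))
  }
  list(values = values, per_scene = per_scene, stats = stats_list,
       recovery = recovery, manifest = cohort$manifest)
}

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

#' Write a consolidated report bundle
#'
#' Writes `values.csv` (per-animal values), `summary.csv` (group, metric, n,
#' mean, sd), `stats.json` (H, global p, per-comparison z / p_raw /
#' p_adjusted / symbol, exclusions) and, when recovery information exists,
#' `recovery.csv`. Column order is fixed and floats are written at 6
#' significant digits so reruns diff cleanly.
#'
#' @param results Output of [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- results$values
  vals$value <- fmt6(vals$value)
  utils::write.csv(vals, file.path(dir, "values.csv"), row.names = FALSE)
  summ <- do.call(rbind, lapply(names(results$stats), function(m) {
    s <- results$stats[[m]]$summary
    data.frame(group = s$group, metric = m, n = s$n,
               mean = fmt6(s$mean), sd = fmt6(s$sd))
  }))
  if (is.null(summ)) {
    summ <- data.frame(group = character(0), metric = character(0),
                       n = integer(0), mean = numeric(0), sd = numeric(0))
  }
  utils::write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  stats_obj <- lapply(results$stats, function(s) {
    list(H = fmt6(s$H), df = s$df, p_global = fmt6(s$p_global),
         alpha = s$alpha,
         comparisons = lapply(seq_len(nrow(s$comparisons)), function(i) {
           r <- s$comparisons[i, ]
           list(comparison = r$comparison, z = fmt6(r$z),
                p_raw = fmt6(r$p_raw), p_adjusted = fmt6(r$p_adjusted),
                symbol = r$symbol)
         }),
         excluded_outliers = if (nrow(s$excluded_outliers)) lapply(
           seq_len(nrow(s$excluded_outliers)), function(i) {
             r <- s$excluded_outliers[i, ]
             list(group = r$group, value = fmt6(r$value), G = fmt6(r$G))
           }) else list())
  })
  jsonlite::write_json(stats_obj, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(results$recovery)) {
    rec <- results$recovery
    rec$seeded <- fmt6(rec$seeded)
    rec$recovered <- fmt6(rec$recovered)
    rec$relative_error <- fmt6(rec$relative_error)
    utils::write.csv(rec, file.path(dir, "recovery.csv"), row.names = FALSE)
  }
  invisible(dir)
}
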