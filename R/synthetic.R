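#' Shape parameters for a synthetic microglial cell
#'
#' Parameterises the resting-to-activated morphology continuum. A cell is a
#' rasterized soma disk plus branched processes grown as random walks. The
#' `retraction` parameter moves the shape from fully ramified (`0`: small
#' soma, long thin processes, low RI) to fully amoeboid (`1`: hypertrophic
#' soma, processes retracted, RI near 1):
#' soma radius scales by `(1 + retraction)`, process length by
#' `(1 - retraction)`, and the process count by `(1 - 0.99 * retraction)`
#' (both stochastically rounded per cell, so the expected values follow the
#' scaling exactly and the family's mean RI varies continuously with
#' `retraction`).
#'
#' @param soma_radius_um Soma radius at `retraction = 0`, micrometres.
#' @param n_processes Number of primary processes at `retraction = 0`.
#' @param process_length_um Process length at `retraction = 0`, micrometres.
#' @param process_thickness_um Process thickness (diameter), micrometres.
#' @param retraction Activation state in `[0, 1]`.
#' @param wiggle SD (radians) of the per-step direction perturbation of the
#'   process random walk; larger values give curlier processes.
#' @return An object of class `cell_shape_params`.
#' @export
cell_shape_params <- function(soma_radius_um = 5, n_processes = 6,
                              process_length_um = 25,
                              process_thickness_um = 1.5,
                              retraction = 0, wiggle = 0.25) {
  stopifnot(soma_radius_um > 0, n_processes >= 0, process_length_um >= 0,
            retraction >= 0, retraction <= 1, wiggle >= 0)
  if (n_processes > 0 && process_thickness_um <= 0) {
    stop("process_thickness_um must be > 0 when n_processes > 0")
  }
  structure(list(soma_radius_um = soma_radius_um, n_processes = n_processes,
                 process_length_um = process_length_um,
                 process_thickness_um = process_thickness_um,
                 retraction = retraction, wiggle = wiggle),
            class = "cell_shape_params")
}

# run code under a fixed seed, restoring the caller's RNG stream afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pixels whose centres fall within `r` um of any of the stamp centres
# (sx, sy in um); each stamp also contributes the pixel containing it, so a
# zero-radius stamp still marks the path. Returns 0-based (x, y) rows.
stamp_disk_pixels <- function(sx, sy, r, ps) {
  x0 <- floor(sx / ps); y0 <- floor(sy / ps)
  m <- ceiling(r / ps) + 1L
  offs <- expand.grid(dx = -m:m, dy = -m:m)
  n <- length(sx)
  cx <- rep(x0, each = nrow(offs)) + offs$dx
  cy <- rep(y0, each = nrow(offs)) + offs$dy
  scx <- rep(sx, each = nrow(offs)); scy <- rep(sy, each = nrow(offs))
  keep <- ((cx + 0.5) * ps - scx)^2 + ((cy + 0.5) * ps - scy)^2 <= r^2 |
    (offs$dx == 0L & offs$dy == 0L)
  cbind(x = cx[keep], y = cy[keep])
}

#' Generate the pixel mask of one synthetic microglial cell
#'
#' Rasterizes a soma disk centred at the origin plus `n_processes` branches
#' grown as unit-micrometre-step random walks attached to the soma boundary
#' at quasi-uniform angles, each dilated to the configured thickness. The
#' resulting pixel set is 4-connected.
#'
#' Uses the current RNG stream; seed it for reproducibility.
#'
#' @param params A [cell_shape_params()].
#' @param pixel_size_um Pixel edge length (the soma must span >= 3 pixels).
#' @return Integer matrix of 0-based `(x, y)` pixel coordinates relative to
#'   the soma centre (coordinates may be negative).
#' @export
make_cell_mask <- function(params, pixel_size_um = 1) {
  stopifnot(inherits(params, "cell_shape_params"), pixel_size_um > 0)
  ps <- pixel_size_um
  ret <- params$retraction
  r_s <- params$soma_radius_um * (1 + ret)
  if (r_s / ps < 1.5) {
    stop("soma must span at least 3 pixels; decrease pixel_size_um")
  }
  # stochastic rounding keeps the expected process count/length equal to the
  # scaling formulas while making the family's mean RI continuous in
  # `retraction` (deterministic rounding makes it a step function, which the
  # +-0.02 calibration tolerance cannot resolve)
  sround <- function(x) floor(x) + (stats::runif(1) < x - floor(x))
  n_eff <- sround(params$n_processes * (1 - 0.99 * ret))
  plen <- params$process_length_um * (1 - ret)
  r_t <- params$process_thickness_um / 2

  # soma disk
  m <- ceiling(r_s / ps) + 1L
  g <- expand.grid(x = -m:m, y = -m:m)
  soma <- ((g$x + 0.5) * ps)^2 + ((g$y + 0.5) * ps)^2 <= r_s^2
  px <- cbind(x = g$x[soma], y = g$y[soma])

  if (n_eff > 0 && plen > 0) {
    for (k in seq_len(n_eff)) {
      nsteps <- sround(plen)
      if (nsteps == 0L) next
      a0 <- 2 * pi * (k - 1) / n_eff +
        stats::runif(1, -pi / (2 * n_eff), pi / (2 * n_eff))
      dirs <- a0 + cumsum(stats::rnorm(nsteps, 0, params$wiggle))
      sx <- (r_s - r_t) * cos(a0) + cumsum(cos(dirs))
      sy <- (r_s - r_t) * sin(a0) + cumsum(sin(dirs))
      sx <- c((r_s - r_t) * cos(a0), sx)
      sy <- c((r_s - r_t) * sin(a0), sy)
      # half-pixel substeps so the rasterized path has no gaps
      nsub <- max(2L, ceiling(1 / (0.5 * ps)) + 1L)
      t <- seq(0, 1, length.out = nsub)
      nseg <- length(sx) - 1L
      ssx <- rep(sx[-length(sx)], each = nsub) +
        rep(diff(sx), each = nsub) * rep(t, nseg)
      ssy <- rep(sy[-length(sy)], each = nsub) +
        rep(diff(sy), each = nsub) * rep(t, nseg)
      branch <- stamp_disk_pixels(ssx, ssy, r_t, ps)
      # bridge diagonal moves of the path spine to guarantee 4-connectivity
      bx <- floor(ssx / ps); by <- floor(ssy / ps)
      dgl <- which(abs(diff(bx)) == 1 & abs(diff(by)) == 1)
      if (length(dgl)) {
        branch <- rbind(branch, cbind(x = bx[dgl + 1L], y = by[dgl]))
      }
      px <- rbind(px, branch)
    }
  }
  px <- unique(px)
  if (nrow(px) == 0L) stop("shape parameters produced an empty mask")
  storage.mode(px) <- "integer"
  px
}

#' Calibrate the retraction parameter to a target mean RI
#'
#' Mean RI of the shape family is a monotone function of `retraction` (by
#' construction); this inverts it by bisection. Each evaluation draws
#' `n_cells` cells under a fixed internal seed (common random numbers, so
#' the objective is deterministic and monotone) and measures their mean RI
#' with the hull-based morphometry.
#'
#' @param target_mean_ri Target mean RI in `(0, 1]`.
#' @param base A [cell_shape_params()] (its `retraction` is ignored).
#' @param pixel_size_um Pixel size used for rasterization.
#' @param n_cells Cells per objective evaluation.
#' @param tol Convergence tolerance on the mean RI (default 0.02).
#' @param seed Internal seed for the common-random-number draws.
#' @return The calibrated retraction value in `[0, 1]`.
#' @export
calibrate_retraction <- function(target_mean_ri, base = cell_shape_params(),
                                 pixel_size_um = 1, n_cells = 25,
                                 tol = 0.02, seed = 760013) {
  stopifnot(target_mean_ri > 0, target_mean_ri <= 1)
  f <- function(ret) {
    p <- base
    p$retraction <- ret
    with_preserved_seed(seed, {
      mean(vapply(seq_len(n_cells), function(i) {
        mask_morphometry(make_cell_mask(p, pixel_size_um), pixel_size_um)$RI
      }, numeric(1)))
    })
  }
  f0 <- f(0); f1 <- f(1)
  if (target_mean_ri < f0 - tol || target_mean_ri > f1 + tol) {
    stop(sprintf(
      "calibration error: target mean RI %.3f outside achievable [%.3f, %.3f]",
      target_mean_ri, f0, f1))
  }
  if (abs(f0 - target_mean_ri) <= tol) return(0)
  if (abs(f1 - target_mean_ri) <= tol) return(1)
  lo <- 0; hi <- 1; mid <- 0.5
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target_mean_ri) <= tol) return(mid)
    if (fm < target_mean_ri) lo <- mid else hi <- mid
  }
  warning("retraction calibration did not reach tolerance; returning midpoint")
  mid
}

# truncated-normal draw by rejection, clamped as a last resort
rtrunc1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:200) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Render one synthetic DAB-like scene
#'
#' Places `n_cells` cells inside the ROI by Poisson-disk (dart-throwing)
#' sampling with a minimum centroid separation, rasterizes each cell, and
#' draws a grayscale image: foreground pixels at `Normal(mu_fg, sigma)`,
#' background at `Normal(mu_bg, sigma)` with `mu_fg < mu_bg` (DAB signal is
#' dark on a bright counterstain after grayscale conversion), clipped to
#' `[0, 255]` and rounded to integers.
#'
#' Uses the current RNG stream; seed it for reproducibility.
#'
#' @param n_cells Number of cells to place.
#' @param params A [cell_shape_params()] shared by all cells.
#' @param roi A [roi_polygon()] defining the placement/evaluation region.
#' @param shape Image dimensions `c(height, width)` in pixels.
#' @param pixel_size_um Pixel edge length, micrometres.
#' @param staining List with `mu_fg`, `mu_bg`, `sigma` (defaults 70/210/12).
#' @param min_sep_um Minimum centroid separation; the default is twice the
#'   maximum radial reach of a cell at the given parameters
#'   (`2 * (soma radius * (1 + retraction) + process length *
#'   (1 - retraction) + process thickness)`), which guarantees cell masks
#'   cannot merge, so component counting has unambiguous ground truth.
#'   Merged microgliosis plaques are deliberately not emulated.
#' @param max_tries Dart-throwing attempts per cell before giving up.
#' @param name Scene identifier.
#' @return List with `image` (a [gray_image()]) and `truth` — a `scene_truth`
#'   list holding `cell_centroids` (n x 2, pixel units), `cell_masks` (list
#'   of 0-based pixel matrices), `true_count`, `true_density_cells_per_mm2`,
#'   `true_positive_fraction_pct` (% of ROI pixels that are foreground) and
#'   `true_ri_per_cell`.
#' @export
render_scene <- function(n_cells, params, roi, shape = c(640, 640),
                         pixel_size_um = 1,
                         staining = list(mu_fg = 70, mu_bg = 210, sigma = 12),
                         min_sep_um = NULL, max_tries = 200L,
                         name = "scene") {
  stopifnot(inherits(params, "cell_shape_params"), inherits(roi, "roi_polygon"),
            n_cells >= 0, staining$mu_fg < staining$mu_bg)
  ny <- shape[1]; nx <- shape[2]
  ps <- pixel_size_um
  roi_mask <- rasterize_roi(roi, shape)
  if (is.null(min_sep_um)) {
    # twice the maximum radial reach of one cell, so masks can never touch
    reach <- params$soma_radius_um * (1 + params$retraction) +
      params$process_length_um * (1 - params$retraction) +
      params$process_thickness_um
    min_sep_um <- 2 * (reach + 2 * pixel_size_um)
  }
  min_sep_px <- min_sep_um / ps

  # Poisson-disk placement of centroids inside the ROI
  bb <- apply(roi$vertices, 2, range)
  acc_x <- numeric(0); acc_y <- numeric(0)
  tries <- 0L
  while (length(acc_x) < n_cells) {
    if (tries > max_tries * max(n_cells, 1L)) {
      stop(sprintf(
        "placement error: only %d of %d cells placed at min separation %.1f um",
        length(acc_x), n_cells, min_sep_um))
    }
    tries <- tries + 1L
    cx <- stats::runif(1, bb[1, 1], bb[2, 1])
    cy <- stats::runif(1, bb[1, 2], bb[2, 2])
    r <- floor(cy) + 1L; cc <- floor(cx) + 1L
    if (r < 1L || r > ny || cc < 1L || cc > nx || !roi_mask[r, cc]) next
    if (length(acc_x) &&
        min((acc_x - cx)^2 + (acc_y - cy)^2) < min_sep_px^2) next
    acc_x <- c(acc_x, cx); acc_y <- c(acc_y, cy)
  }

  fg <- matrix(FALSE, ny, nx)
  cell_masks <- vector("list", n_cells)
  true_ri <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    loc <- make_cell_mask(params, ps)
    gx <- loc[, 1] + round(acc_x[i]); gy <- loc[, 2] + round(acc_y[i])
    keep <- gx >= 0L & gx < nx & gy >= 0L & gy < ny
    gpx <- cbind(x = gx[keep], y = gy[keep])
    cell_masks[[i]] <- gpx
    true_ri[i] <- mask_morphometry(gpx, ps)$RI
    fg[gpx[, 2] + 1L + gpx[, 1] * ny] <- TRUE
  }

  img <- matrix(stats::rnorm(ny * nx, staining$mu_bg, staining$sigma), ny, nx)
  if (any(fg)) img[fg] <- stats::rnorm(sum(fg), staining$mu_fg, staining$sigma)
  img <- pmin(pmax(round(img), 0), 255)

  truth <- structure(list(
    cell_centroids = cbind(x = acc_x, y = acc_y),
    cell_masks = cell_masks,
    true_count = n_cells,
    true_density_cells_per_mm2 = n_cells / roi_area_mm2(roi, ps),
    true_positive_fraction_pct = 100 * sum(fg & roi_mask) / sum(roi_mask),
    true_ri_per_cell = true_ri
  ), class = "scene_truth")
  list(image = gray_image(img, ps, name = name), truth = truth, roi = roi)
}

#' Group specification for a synthetic cohort
#'
#' Exactly one of `target_density` (cells/mm^2) or `target_positive_pct`
#' (% positive area) drives the number of cells per scene; the other is
#' recorded as achieved. `target_mean_ri` drives the morphology via
#' [calibrate_retraction()]. Per-animal targets are drawn as
#' `Normal(target, sd)` truncated to their valid ranges.
#'
#' @param label Group label, e.g. `"Ctrl"`, `"1w"`, `"3w"`, `"5w"`.
#' @param n_animals Animals (scenes) in the group, `>= 2`.
#' @param target_mean_ri Group mean RI in `(0, 1]`.
#' @param sd_ri Between-animal SD of the RI target.
#' @param target_density Group mean density in cells/mm^2, or `NULL`.
#' @param sd_density Between-animal SD of the density target.
#' @param target_positive_pct Group mean % positive area in `(0, 100)`, or
#'   `NULL`.
#' @param sd_pct Between-animal SD of the % target.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, n_animals = 5, target_mean_ri, sd_ri = 0,
                       target_density = NULL, sd_density = 0,
                       target_positive_pct = NULL, sd_pct = 0) {
  stopifnot(n_animals >= 2, target_mean_ri > 0, target_mean_ri <= 1,
            sd_ri >= 0, sd_density >= 0, sd_pct >= 0)
  if (is.null(target_density) == is.null(target_positive_pct)) {
    stop("give exactly one of `target_density` or `target_positive_pct`")
  }
  if (!is.null(target_density) && target_density <= 0) {
    stop("target_density must be > 0")
  }
  if (!is.null(target_positive_pct) &&
      (target_positive_pct <= 0 || target_positive_pct >= 100)) {
    stop("target_positive_pct must lie in (0, 100)")
  }
  structure(list(label = label, n_animals = as.integer(n_animals),
                 target_mean_ri = target_mean_ri, sd_ri = sd_ri,
                 target_density = target_density, sd_density = sd_density,
                 target_positive_pct = target_positive_pct, sd_pct = sd_pct),
            class = "group_spec")
}

#' Cohort specification
#'
#' @param groups List of [group_spec()] objects.
#' @param seed Root seed; per-animal RNG streams are derived from it (see
#'   Details), so generation is reproducible and order-independent.
#' @param image_shape Scene dimensions `c(height, width)`, pixels.
#' @param pixel_size_um Pixel size, micrometres.
#' @param base_params Base [cell_shape_params()] of the shape family.
#' @param roi_margin_px Inset of the rectangular evaluation ROI from the
#'   image border (keeps cells clear of the border-exclusion rule).
#' @param staining Staining model passed to [render_scene()].
#' @details Per-animal seeds are derived as
#'   `(seed * 100003 + group_index * 1009 + animal_index * 7) mod (2^31 - 2) + 1`,
#'   so each animal owns an independent reproducible stream.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed, image_shape = c(640, 640),
                        pixel_size_um = 1,
                        base_params = cell_shape_params(),
                        roi_margin_px = 20,
                        staining = list(mu_fg = 70, mu_bg = 210, sigma = 12)) {
  stopifnot(length(groups) >= 1, all(vapply(groups, inherits, logical(1),
                                            "group_spec")))
  structure(list(groups = groups, seed = as.integer(seed),
                 image_shape = image_shape, pixel_size_um = pixel_size_um,
                 base_params = base_params, roi_margin_px = roi_margin_px,
                 staining = staining),
            class = "cohort_spec")
}

animal_seed <- function(root, g, a) {
  as.integer((as.double(root) * 100003 + g * 1009 + a * 7) %% (2^31 - 2)) + 1L
}

#' Generate a synthetic cohort with ground truth
#'
#' For every animal: draw the per-animal targets from the group
#' distribution, calibrate the retraction to the animal's RI target, derive
#' the cell count from the density (or % positive area) target, and render
#' one scene. Fully reproducible from the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `scenes` (list of per-animal lists: `image`, `roi`,
#'   `truth`, `group`, `animal`), `manifest` (one data-frame row per animal:
#'   group, animal, name, targets drawn, true_count, true_density, true_pct,
#'   true_mean_ri, retraction) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  m <- spec$roi_margin_px
  roi <- roi_polygon(rbind(c(m, m), c(nx - m, m), c(nx - m, ny - m),
                           c(m, ny - m)))
  roi_mm2 <- roi_area_mm2(roi, spec$pixel_size_um)
  roi_px <- abs(shoelace_area(roi$vertices))
  scenes <- list()
  rows <- list()
  for (g in seq_along(spec$groups)) {
    gs <- spec$groups[[g]]
    for (a in seq_len(gs$n_animals)) {
      sd_ga <- animal_seed(spec$seed, g, a)
      res <- with_preserved_seed(sd_ga, {
        ri_t <- rtrunc1(gs$target_mean_ri, gs$sd_ri, 0.02, 0.995)
        ret <- calibrate_retraction(ri_t, spec$base_params,
                                    spec$pixel_size_um, seed = sd_ga + 1L)
        p <- spec$base_params
        p$retraction <- ret
        if (!is.null(gs$target_density)) {
          dens_t <- rtrunc1(gs$target_density, gs$sd_density, 1, Inf)
          n <- max(0L, round(dens_t * roi_mm2))
          pct_t <- NA_real_
        } else {
          pct_t <- rtrunc1(gs$target_positive_pct, gs$sd_pct, 0.05, 99)
          mean_px <- with_preserved_seed(sd_ga + 2L, {
            mean(vapply(1:15, function(i)
              nrow(make_cell_mask(p, spec$pixel_size_um)), numeric(1)))
          })
          n <- max(1L, round(pct_t / 100 * roi_px / mean_px))
          dens_t <- NA_real_
        }
        sc <- render_scene(n, p, roi, spec$image_shape, spec$pixel_size_um,
                           spec$staining,
                           name = sprintf("%s_animal%02d", gs$label, a))
        list(sc = sc, ri_t = ri_t, ret = ret, dens_t = dens_t, pct_t = pct_t)
      })
      tr <- res$sc$truth
      scenes[[length(scenes) + 1L]] <- list(
        image = res$sc$image, roi = roi, truth = tr,
        group = gs$label, animal = a)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gs$label, animal = a, name = res$sc$image$name,
        target_ri = res$ri_t, retraction = res$ret,
        target_density = res$dens_t, target_pct = res$pct_t,
        true_count = tr$true_count,
        true_density = tr$true_density_cells_per_mm2,
        true_pct = tr$true_positive_fraction_pct,
        true_mean_ri = mean(tr$true_ri_per_cell))
    }
  }
  list(scenes = scenes, manifest = do.call(rbind, rows), spec = spec)
}

#' Read a cohort specification from YAML
#'
#' The YAML mirrors [cohort_spec()] field-for-field: top-level `seed`,
#' optional `image_shape`, `pixel_size_um`, `roi_margin_px`, `staining`,
#' `base_params`, and a `groups` list whose entries mirror [group_spec()].
#'
#' @param path YAML file path.
#' @return A [cohort_spec()].
#' @export
read_cohort_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed) || is.null(y$groups)) {
    stop("cohort YAML needs `seed` and `groups`")
  }
  groups <- lapply(y$groups, function(g) do.call(group_spec, g))
  args <- list(groups = groups, seed = y$seed)
  for (f in c("image_shape", "pixel_size_um", "roi_margin_px", "staining")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$base_params)) {
    args$base_params <- do.call(cell_shape_params, y$base_params)
  }
  do.call(cohort_spec, args)
}

#' Write a generated cohort to disk
#'
#' Emits one PNG scene and one JSON ROI per animal, a `manifest.csv` linking
#' them to their ground truth, and a `truth_cells.csv` with per-cell ground
#' truth (group, animal, cell, centroid, area, RI).
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$file <- paste0(man$name, ".png")
  man$roi_file <- paste0(man$name, "_roi.json")
  cells <- list()
  for (i in seq_along(cohort$scenes)) {
    sc <- cohort$scenes[[i]]
    write_image_png(sc$image, file.path(dir, man$file[i]))
    write_roi_json(sc$roi, file.path(dir, man$roi_file[i]),
                   pixel_size_um = sc$image$pixel_size_um)
    tr <- sc$truth
    if (tr$true_count > 0) {
      cells[[i]] <- data.frame(
        group = sc$group, animal = sc$animal,
        cell = seq_len(tr$true_count),
        centroid_x = tr$cell_centroids[, 1],
        centroid_y = tr$cell_centroids[, 2],
        area_px = vapply(tr$cell_masks, nrow, integer(1)),
        true_ri = tr$true_ri_per_cell)
    }
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, cells), file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  invisible(dir)
}
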