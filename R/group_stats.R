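#' Arithmetic mean and sample SD
#'
#' Group-level values are reported as mean plus/minus SD with the `n - 1`
#' denominator (the convention of common analysis software).
#'
#' @param values Numeric vector with at least two finite values.
#' @return List with `mean`, `sd` and `n`.
#' @export
summarize_values <- function(values) {
  if (length(values) < 2L || !all(is.finite(values))) {
    stop("need >= 2 finite values")
  }
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}

#' Grubbs' test for a single outlier
#'
#' Classic two-sided, single-pass Grubbs: the test statistic is
#' `G = max |x_i - mean| / SD`, and the critical value at level `alpha` is
#' `((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t` the upper
#' `alpha / (2 n)` quantile of Student's t on `n - 2` degrees of freedom.
#' At most one value is flagged. Used to screen densitometric % area values
#' before group testing.
#'
#' @param values Numeric vector, `n >= 3`, not all equal.
#' @param alpha Significance level (default 0.05).
#' @return List with `outlier_index` (`NA` when none flagged),
#'   `outlier_value`, `G` and `G_critical`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) stop("Grubbs' test needs n >= 3")
  s <- stats::sd(values)
  if (s == 0) {
    warning("all values equal; Grubbs' test not applicable")
    return(list(outlier_index = NA_integer_, outlier_value = NA_real_,
                G = NA_real_, G_critical = NA_real_))
  }
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  G <- dev[i] / s
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  G_crit <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
  if (G > G_crit) {
    list(outlier_index = i, outlier_value = values[i], G = G,
         G_critical = G_crit)
  } else {
    list(outlier_index = NA_integer_, outlier_value = NA_real_, G = G,
         G_critical = G_crit)
  }
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-group comparison with mid-ranks for ties, tie-corrected H
#' and a chi-square upper-tail p-value on `k - 1` degrees of freedom
#' (delegates to [stats::kruskal.test()]). Degenerate input (all pooled
#' values identical) returns `H = 0`, `p = 1`.
#'
#' @param values Numeric vector of pooled per-animal values.
#' @param groups Group label for each value.
#' @return List with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 values")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's post hoc comparisons against a control group
#'
#' For each non-control group g the z statistic is
#' `z = (meanrank_g - meanrank_ctrl) / sqrt((N (N + 1) / 12 - T) *
#' (1 / n_g + 1 / n_ctrl))` with tie correction
#' `T = sum(t^3 - t) / (12 (N - 1))` over tied-value multiplicities, mid-ranks
#' over the pooled sample, two-sided normal p-values, and Bonferroni-type
#' adjustment `p_adj = min(1, m * p_raw)` over the `m` comparisons made —
#' matching the vs-control design of common graphing software. An all-pairs
#' mode is available.
#'
#' @param values Numeric vector of pooled per-animal values.
#' @param groups Group label for each value.
#' @param control Label of the control group.
#' @param mode `"vs_control"` (default) or `"all_pairs"`.
#' @return Data frame with columns `comparison`, `z`, `p_raw`, `p_adjusted`,
#'   `symbol`.
#' @export
dunns_test <- function(values, groups, control, mode = c("vs_control",
                                                         "all_pairs")) {
  mode <- match.arg(mode)
  groups <- as.character(groups)
  labs <- unique(groups)
  if (!control %in% labs) stop("control group '", control, "' not present")
  if (length(labs) < 2L) stop("need >= 2 groups")
  N <- length(values)
  r <- rank(values)               # mid-ranks
  tt <- table(values)
  T_tie <- sum(tt^3 - tt) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - T_tie
  mr <- tapply(r, groups, mean)
  nn <- tapply(r, groups, length)
  pairs <- if (mode == "vs_control") {
    lapply(setdiff(labs, control), function(g) c(g, control))
  } else {
    utils::combn(labs, 2, simplify = FALSE)
  }
  m <- length(pairs)
  out <- lapply(pairs, function(pr) {
    g1 <- pr[1]; g2 <- pr[2]
    se <- sqrt(v0 * (1 / nn[[g1]] + 1 / nn[[g2]]))
    z <- if (se > 0) (mr[[g1]] - mr[[g2]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = paste(g1, "vs", g2), z = z, p_raw = p,
               p_adjusted = min(1, m * p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$symbol <- vapply(res$p_adjusted, significance_symbol, character(1))
  rownames(res) <- NULL
  res
}

#' Significance symbol for a p-value
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, otherwise
#' `n.s.` (boundaries inclusive).
#'
#' @param p A p-value in `[0, 1]`.
#' @return Character symbol.
#' @export
significance_symbol <- function(p) {
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
    stop("p must lie in [0, 1]")
  }
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else "n.s."
}

#' Full group-level analysis of one metric
#'
#' Applies the group-testing pipeline to a per-animal value table: Grubbs'
#' outlier exclusion per group (only for the densitometric `percent_area`
#' metric — morphology and density values are never screened), then
#' Kruskal-Wallis, then Dunn's comparisons against the control group with
#' significance symbols.
#'
#' @param data Data frame with columns `group` and `value` (one row per
#'   animal).
#' @param metric One of `"density"`, `"percent_area"`, `"mean_ri"`.
#' @param control Label of the control group.
#' @param alpha Level for Grubbs' screening (default 0.05).
#' @return A `test_result` list: `metric`, `summary` (per-group n/mean/sd),
#'   `H`, `df`, `p_global`, `comparisons` (Dunn's table), `alpha`,
#'   `excluded_outliers` (data frame: group, value, G).
#' @export
run_group_analysis <- function(data, metric = c("mean_ri", "density",
                                                "percent_area"),
                               control = "Ctrl", alpha = 0.05) {
  metric <- match.arg(metric)
  stopifnot(all(c("group", "value") %in% names(data)))
  excluded <- data.frame(group = character(0), value = numeric(0),
                         G = numeric(0))
  if (metric == "percent_area") {
    keep <- rep(TRUE, nrow(data))
    for (g in unique(data$group)) {
      idx <- which(data$group == g)
      if (length(idx) < 3L || stats::sd(data$value[idx]) == 0) next
      gr <- grubbs_test(data$value[idx], alpha)
      if (!is.na(gr$outlier_index)) {
        keep[idx[gr$outlier_index]] <- FALSE
        excluded <- rbind(excluded, data.frame(
          group = g, value = gr$outlier_value, G = gr$G))
      }
    }
    data <- data[keep, , drop = FALSE]
  }
  kw <- kruskal_wallis(data$value, data$group)
  cmp <- dunns_test(data$value, data$group, control)
  summ <- do.call(rbind, lapply(split(data$value, data$group), function(v) {
    s <- summarize_values(v)
    data.frame(n = s$n, mean = s$mean, sd = s$sd)
  }))
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL)
  structure(list(metric = metric, summary = summ, H = kw$H, df = kw$df,
                 p_global = kw$p, comparisons = cmp, alpha = alpha,
                 excluded_outliers = excluded),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> metric %s: H = %.4f (df %d), p = %.4g\n",
              x$metric, x$H, x$df, x$p_global))
  print(x$comparisons, ...)
  if (nrow(x$excluded_outliers)) {
    cat("excluded outliers:\n"); print(x$excluded_outliers, ...)
  }
  invisible(x)
}
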