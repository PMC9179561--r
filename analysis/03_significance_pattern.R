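#!/usr/bin/env Rscript
# Step 3: reproduce the qualitative significance progression of the
# white-matter ramification index (non-significant at 1 week, significant
# at 3 and 5 weeks of cuprizone intoxication vs control) as a Monte-Carlo
# experiment: 100 replicate cohorts of per-animal mean RI drawn at the
# published corpus-callosum group means/SDs, each analysed with
# Kruskal-Wallis + Dunn's vs-control comparisons. Writes
# results/pattern_reproduction.csv and a cross-region significance table
# from the step-2 reports.

library(microgliaq)

set.seed(3301)
groups <- rep(c("Ctrl", "1w", "3w", "5w"), each = 5)
means <- c(Ctrl = 0.66, `1w` = 0.81, `3w` = 0.87, `5w` = 0.88)
sds <- c(Ctrl = 0.04, `1w` = 0.06, `3w` = 0.03, `5w` = 0.04)

hits <- replicate(100, {
  v <- stats::rnorm(20, means[groups], sds[groups])
  d <- run_group_analysis(data.frame(group = groups, value = v),
                          "mean_ri", control = "Ctrl")$comparisons
  stats::setNames(d$p_adjusted <= 0.05, d$comparison)
})
rates <- rowMeans(hits)
pat <- data.frame(comparison = names(rates), significant_fraction = rates,
                  row.names = NULL)
dir.create("results", showWarnings = FALSE)
utils::write.csv(pat, file.path("results", "pattern_reproduction.csv"),
                 row.names = FALSE)
cat("White-matter RI significance rates over 100 replicate cohorts:\n")
print(pat, row.names = FALSE)
cat("(published pattern: 1 w n.s.; 3 w and 5 w significant)\n\n")

# consolidated symbol table from the per-region reports of step 2
rows <- list()
for (rg in list.dirs("results", recursive = FALSE)) {
  f <- file.path(rg, "stats.json")
  if (!file.exists(f)) next
  st <- jsonlite::read_json(f)
  for (m in names(st)) for (cmp in st[[m]]$comparisons) {
    rows[[length(rows) + 1L]] <- data.frame(
      region = basename(rg), metric = m, comparison = cmp$comparison,
      p_adjusted = cmp$p_adjusted, symbol = cmp$symbol)
  }
}
if (length(rows)) {
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path("results", "significance_table.csv"),
                   row.names = FALSE)
  cat("Cross-region significance table (from step 2 reports):\n")
  print(tab, row.names = FALSE)
}
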