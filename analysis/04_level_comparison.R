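#!/usr/bin/env Rscript
# Stage 4: compare every centrality measure across the three age levels with
# Kruskal-Wallis tests, pooling animals from all pens of a level, and attach
# significance letters from pairwise two-group rank tests (p < 0.05): levels
# that do not share a letter differ significantly.

suppressPackageStartupMessages(library(agonet))

records <- readr::read_csv("results/centrality.csv", show_col_types = FALSE)
summary_tbl <- compare_levels(records)
readr::write_csv(summary_tbl, "results/level_summary.csv")

cat("median (range) per level, letters from pairwise rank tests:\n")
for (m in unique(summary_tbl$measure)) {
  rows <- summary_tbl[summary_tbl$measure == m, ]
  cells <- sprintf("%.2f^%s (%.2f-%.2f)", rows$median, rows$letter,
                   rows$min, rows$max)
  cat(sprintf("  %-24s %s | X^2(%d) = %.2f, p %s\n", m,
              paste(cells, collapse = "  "), rows$df[1], rows$H[1],
              format_p_value(rows$p_value[1])))
}
cat("wrote results/level_summary.csv\n")
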