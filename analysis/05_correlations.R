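#!/usr/bin/env Rscript
# Stage 5: Spearman rank correlations (a) between measures within each age
# level (binary vs weighted variants, in- vs out-degree, degree family vs
# betweenness and closeness families) and (b) of each measure between
# consecutive age levels for the animals tracked through the whole study.

suppressPackageStartupMessages(library(agonet))

records <- readr::read_csv("results/centrality.csv", show_col_types = FALSE)
trajectories <- read_trajectories("results/synthetic/trajectories.csv")

within <- do.call(rbind, lapply(age_levels(), function(lv)
  within_level_correlations(records, lv)))
readr::write_csv(within, "results/within_level_correlations.csv")

cross <- cross_level_correlations(records, trajectories)
readr::write_csv(cross, "results/cross_level_correlations.csv")

bvw <- within[within$var1 == "degree_binary" & within$var2 == "degree_weighted", ]
cat("binary vs weighted degree within levels: ",
    sprintf("%s rho = %.2f", bvw$age_level, bvw$rho), "\n")
cat("consecutive-level correlations (tracked animals only):\n")
for (m in c("degree_binary", "out_degree_binary", "out_closeness_binary")) {
  rows <- cross[cross$measure == m, ]
  cat(sprintf("  %-22s %s-%s rho = %5.2f (n = %d, p %s)\n",
              m, rows$level_from, rows$level_to, rows$rho, rows$n,
              format_p_value(rows$p_value)))
}
cat("wrote results/within_level_correlations.csv and results/cross_level_correlations.csv\n")
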