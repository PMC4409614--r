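#!/usr/bin/env Rscript
# Stage 3: compute all 14 centrality measures (7 measures x binary/weighted)
# for every animal of every pen. Binary measures count distinct opponents
# and presence of links; weighted measures use fight frequencies, with
# shortest-path edge length 1/weight so frequent opponents are "close".

suppressPackageStartupMessages(library(agonet))

events <- filter_events(read_events("results/synthetic/events.csv"))
roster <- read_roster("results/synthetic/roster.csv")

records <- centrality_table(build_networks(events, roster))
readr::write_csv(records, "results/centrality.csv")

cat(sprintf("centrality table: %d animals x %d measures\n",
            nrow(records), length(centrality_measures())))
med <- aggregate(records[centrality_measures()],
                 by = list(level = records$age_level), median)
med <- med[match(age_levels(), med$level), ]
for (m in c("degree_binary", "degree_weighted", "betweenness_binary",
            "closeness_binary")) {
  cat(sprintf("  median %-22s %6.2f (weaned) %6.2f (growing) %6.2f (gilt)\n",
              m, med[[m]][1], med[[m]][2], med[[m]][3]))
}
cat("wrote results/centrality.csv\n")
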