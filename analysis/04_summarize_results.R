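#!/usr/bin/env Rscript

# Step 4: headline tables.
#
# Condenses the burden report into the tables a reader would scan first:
# global 2019 counts and age-standardized rates per measure with 95%
# uncertainty intervals, the cancer-group ranking by DALYs, YLL/YLD shares,
# and the 2010 -> 2019 changes (total percent and annualized) in
# age-standardized rates.

suppressMessages({library(oncoburden); library(data.table)})

est <- fread("results/pipeline/burden_report.csv")
chg <- fread("results/pipeline/burden_changes.csv")
rank <- fread("results/pipeline/ranking.csv")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

fmt <- function(m, l, u) sprintf("%.1f (%.1f-%.1f)", m, l, u)

g19 <- est[location == "global" & sex == "both" & year == 2019]
tab1 <- dcast(g19[metric %in% c("count", "asr")],
              cause ~ measure + metric, value.var = c("mean"))
fwrite(tab1, "results/tables/global_2019.csv")

shares_yll <- g19[measure == "yll" & metric == "count" & cause == "total",
                  mean]
shares_yld <- g19[measure == "yld" & metric == "count" & cause == "total",
                  mean]
message(sprintf("global 2019 (both sexes, all modeled cancers):"))
for (ms in c("deaths", "incidence", "yll", "yld", "daly")) {
  row <- g19[measure == ms & cause == "total" & metric == "count"]
  asr <- g19[measure == ms & cause == "total" & metric == "asr"]
  message(sprintf("  %-9s %10.0f (%.0f-%.0f)   ASR %s", ms, row$mean,
                  row$lower, row$upper, fmt(asr$mean, asr$lower, asr$upper)))
}
message(sprintf("  YLL share of DALYs: %.1f%%; YLD share: %.1f%%",
                100 * shares_yll / (shares_yll + shares_yld),
                100 * shares_yld / (shares_yll + shares_yld)))

message("cancer groups ranked by global DALYs in 2019:")
for (i in seq_len(nrow(rank))) {
  message(sprintf("  %d. %-24s %.0f DALYs", rank$rank[i], rank$cause[i],
                  rank$count[i]))
}

cg <- chg[location == "global" & sex == "both" & cause == "total" &
            metric == "asr"]
message("2010 -> 2019 change in age-standardized rates (global):")
for (i in seq_len(nrow(cg))) {
  message(sprintf("  %-9s %+.1f%% (%+.1f to %+.1f); annualized %+.2f%%/yr",
                  cg$measure[i], cg$pct_mean[i], cg$pct_lower[i],
                  cg$pct_upper[i], cg$arc_mean[i]))
}
fwrite(cg, "results/tables/global_changes.csv")
fwrite(rank, "results/tables/ranking.csv")
message("wrote results/tables/{global_2019,global_changes,ranking}.csv")
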