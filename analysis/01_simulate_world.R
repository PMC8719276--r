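#!/usr/bin/env Rscript

# Step 1: simulate the synthetic study world.
#
# Builds the default world (8 locations x 2000-2019 x 12 age groups x
# 2 sexes x 5 cancer groups) with known ground truth and writes the four
# observation CSVs a real analysis would start from: registry incidence,
# vital-registration deaths (with the C22.9 garbage fraction), population,
# and covariates (HAQ + SDI components).

suppressMessages(library(oncoburden))

seed <- as.integer(Sys.getenv("ONCOBURDEN_SEED", "2019"))
out <- "results/world"

cfg <- world_config(seed = seed)
world <- simulate_world_csvs(cfg, out)

reg <- data.table::fread(file.path(out, "registry.csv"))
vr <- data.table::fread(file.path(out, "vr.csv"))
message(sprintf("world seed %d: %d registry rows (%.0f%% location-year coverage), %d VR rows",
                seed, nrow(reg),
                100 * length(unique(paste(reg$location, reg$year))) /
                  (cfg$n_locations * length(cfg$years)), nrow(vr)))
message(sprintf("garbage-coded (C22.9) deaths: %d of %d liver-coded deaths",
                sum(vr$deaths[vr$icd_code == "C22.9"]),
                sum(vr$deaths[startsWith(vr$icd_code, "C22")])))
message("wrote ", out, "/{registry,vr,population,covariates}.csv")
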