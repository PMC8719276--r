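#!/usr/bin/env Rscript

# Step 2: data preparation.
#
# Reads the simulated observation CSVs, validates them, maps ICD-coded
# deaths to the cancer cause list (dropping Kaposi sarcoma and non-cancer
# codes with an explicit count), redistributes unspecified-liver (C22.9)
# garbage deaths, applies the declared completeness correction, and builds
# the stabilized MIR observations that feed the smoothing model.

suppressMessages({library(oncoburden); library(data.table)})

inp <- "results/world"
out <- "results/prepared"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

registry <- fread(file.path(inp, "registry.csv"))
vr <- fread(file.path(inp, "vr.csv"))
population <- fread(file.path(inp, "population.csv"))
covariates <- fread(file.path(inp, "covariates.csv"))

val <- validate_inputs(list(registry = registry, vr = vr,
                            population = population,
                            covariates = covariates))
stopifnot(length(val$fatal) == 0)
message("validation: no fatal issues, ", length(val$warnings), " warnings")

cfg <- world_config(seed = as.integer(Sys.getenv("ONCOBURDEN_SEED", "2019")))
cmap <- default_cause_map(cfg$cancer_groups)
mv <- map_vr_deaths(vr, cmap)
message(sprintf("mapped deaths: %.0f; garbage C22.9: %.0f; excluded (Kaposi): %.0f; non-cancer: %.0f",
                sum(mv$mapped$deaths), sum(mv$garbage$deaths),
                mv$excluded_deaths, mv$non_cancer_deaths))

deaths <- redistribute_unspecified_liver(mv$mapped, mv$garbage,
                                         proportions = c(liver = 1))
deaths[, deaths := deaths / cfg$vr_completeness]
obs <- suppressWarnings(
  stabilized_mir_observations(registry, deaths, cap = cfg$mir_cap))
message(sprintf("MIR observations: %d (median effective sample size %.0f)",
                nrow(obs), median(obs$ess)))

fwrite(deaths, file.path(out, "deaths_by_cause.csv"))
fwrite(obs, file.path(out, "mir_observations.csv"))
message("wrote ", out, "/{deaths_by_cause,mir_observations}.csv")
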