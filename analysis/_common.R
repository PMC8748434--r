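# Shared settings for the analysis scripts: one synthetic three-stage
# granulosa-cell-style study at the default scale (coarse layer 1,000 bins
# x 20 kb for compartments/TADs; fine layer 1,000 bins x 5 kb for
# promoter-enhancer interactions and loops), seed 1 throughout.

suppressPackageStartupMessages(library(hicdynamics))

STUDY_SEED <- 1L
RESULTS <- file.path("results")
# raw simulated contact maps are bulky; they live under scratch/, only the
# derived result tables go to results/
DATA_DIR <- file.path("scratch", "simdata")

study_config <- function() run_config(seed = STUDY_SEED)

# the simulation is a pure function of its config, so every script can
# rebuild the identical study
get_study <- function() {
  cfg <- study_config()
  simulate_study(cfg$coarse, cfg$fine)
}

tsv <- function(df, name) {
  dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, file.path(RESULTS, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("  wrote ", file.path(RESULTS, name))
}
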