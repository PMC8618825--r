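# Shared setup for the analysis scripts: output locations and the study
# configuration.  Every script can be run from the repository root with
#   Rscript analysis/<script>.R [--seed N]
# and writes its tables under results/.

suppressPackageStartupMessages(library(genorig))

args <- commandArgs(trailingOnly = TRUE)
seed <- 1L
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

res_dir <- "results"
sim_dir <- file.path(res_dir, "sim")
dir.create(sim_dir, showWarnings = FALSE, recursive = TRUE)

config <- read_config(system.file("extdata", "config_default.yaml",
                                  package = "genorig"),
                      seed = seed)

state_file <- function(name) file.path(res_dir, paste0(name, ".rds"))
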