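# Shared settings for the numbered analysis scripts.
# Heavy intermediates live under scratch/ (not tracked as results);
# compact result tables are copied into results/.

library(coexqtl)

RUN_DIR <- "scratch/analysis_run"
RESULTS_DIR <- "results"
SEED <- {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i) == 1 && i < length(args)) as.integer(args[i + 1]) else 1L
}
dir.create(RUN_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

run_path <- function(f) file.path(RUN_DIR, f)
publish <- function(f) invisible(file.copy(run_path(f),
                                           file.path(RESULTS_DIR, f),
                                           overwrite = TRUE))
say <- function(...) cat("[analysis]", ..., "\n")
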