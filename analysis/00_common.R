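# Shared settings for the analysis workflow. Every numbered script can
# be run on its own (later steps read the earlier steps' files from
# results/analysis). The master seed fans out deterministically.

suppressPackageStartupMessages(library(poolnet))

MASTER_SEED <- as.integer(Sys.getenv("POOLNET_SEED", "2024"))
OUT <- "results/analysis"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

study_config <- function() sim_config(seed = MASTER_SEED)

# matrices round-trip through TSV with ids in the first column
read_matrix <- function(file) {
  df <- read_tsv_commented(file.path(OUT, file))
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
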