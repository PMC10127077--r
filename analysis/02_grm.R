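# Step 2 -- pooled-allele-frequency genomic relationship matrices:
# column-centred VanRaden kernel for tetraploid pools, diagonal
# correction for read-sampling noise, and top-10 PC scores used
# downstream for stratification control.

source("analysis/00_common.R")

cfg <- study_config()
for (cl in c("class1", "class2")) {
  F <- read_matrix(paste0("freqs_", cl, ".tsv"))
  pf <- pool_freq(F, ploidy = cfg$ploidy, depth = rep(cfg$depth, nrow(F)))
  grm <- grm_from_frequencies(pf, pcs = 10)
  write_tsv_commented(grm$G, file.path(OUT, paste0("grm_", cl, ".tsv")),
                      sprintf("grm ploidy=%d depth=%g denominator=%.6g",
                              cfg$ploidy, cfg$depth, grm$denominator),
                      rownames_as = "family")
  write_tsv_commented(grm$pc_scores,
                      file.path(OUT, paste0("pcs_", cl, ".tsv")),
                      sprintf("grm PC scores; varfrac10=%.3f",
                              sum(grm$pc_varfrac)),
                      rownames_as = "family")
  message(sprintf(
    "%s: mean diagonal %.3f, mean off-diagonal %.4f, top-10 PCs explain %.0f%%",
    cl, mean(diag(grm$G)), mean(grm$G[row(grm$G) != col(grm$G)]),
    100 * sum(grm$pc_varfrac)))
}
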