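# Step 7 -- omics-assisted prediction: chained random-forest
# imputation of the pool allele frequencies, spatially adjusted family
# BLUEs merged across locations, and random-forest OOB accuracy for
# the hub / random-draw / all-features scenarios per trait and layer.

source("analysis/00_common.R")

snp_map <- read_tsv_commented(file.path(OUT, "snp_map.tsv"))
gene_map <- read_tsv_commented(file.path(OUT, "gene_map.tsv"))

imp <- list(); pheno <- list()
for (cl in c("class1", "class2")) {
  M <- read_matrix(paste0("freqs_", cl, ".tsv"))
  imp[[cl]] <- impute_frequencies_chained_rf(
    M, snp_map$chrom, seed = derive_seed(MASTER_SEED, paste0("imp", cl)))
  pheno[[cl]] <- utils::read.csv(file.path(OUT,
                                           paste0("pheno_", cl, ".csv")))
}
blues <- suppressWarnings(compute_blues(pheno))
write_tsv_commented(blues, file.path(OUT, "blues.tsv"),
                    "predict: centred family BLUEs per location")

hub_gene <- read_tsv_commented(
  file.path(OUT, "conserved_hubs_gene.tsv"))$feature
hub_nmr <- read_tsv_commented(
  file.path(OUT, "conserved_hubs_nmr.tsv"))$feature
hub_snp <- snps_tagging_hubs(gene_map, hub_gene, snp_map)

snp_all <- rbind(imp$class1, imp$class2)
stack_layer <- function(layer) {
  do.call(rbind, lapply(c("class1", "class2"), function(cl)
    t(read_matrix(sprintf("omics_%s_%s.tsv", layer, cl)))))
}
gene_all <- stack_layer("gene")
nmr_all <- stack_layer("nmr")

full_sets <- list(snp = snp_all, gene = gene_all, nmr = nmr_all)
hub_sets <- list(
  snp = snp_all[, intersect(hub_snp, colnames(snp_all)), drop = FALSE],
  gene = gene_all[, intersect(hub_gene, colnames(gene_all)), drop = FALSE],
  nmr = nmr_all[, intersect(hub_nmr, colnames(nmr_all)), drop = FALSE])

y_by_trait <- lapply(split(blues, blues$trait), function(b) {
  y <- stats::setNames(b$blue, b$family)[rownames(snp_all)]
  y
})
keep <- Reduce(`&`, lapply(y_by_trait, function(y) !is.na(y)))
full_sets <- lapply(full_sets, function(m) m[keep, , drop = FALSE])
hub_sets <- lapply(hub_sets, function(m) m[keep, , drop = FALSE])
y_by_trait <- lapply(y_by_trait, function(y) y[keep])

res <- scenario_runner(hub_sets, full_sets, y_by_trait, n_draws = 20,
                       seed = derive_seed(MASTER_SEED, "scenario"),
                       num_trees = 2000)
write_tsv_commented(res, file.path(OUT, "prediction_results.tsv"),
                    "predict: per-forest OOB accuracies")
smry <- summarize_scenarios(res)
write_tsv_commented(smry, file.path(OUT, "prediction_summary.tsv"),
                    "predict: aggregated scenarios")
message(paste(capture.output(print(smry)), collapse = "\n"))
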