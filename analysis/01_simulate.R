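# Step 1 -- generate the synthetic study: two pedigree classes of
# tetraploid family pools connected through shared perenne parents,
# pooled allele frequencies with sampling noise and missingness,
# network-structured gene and NMR layers with planted hubs, and
# plot-level phenotypes genetically correlated with designated hubs.

source("analysis/00_common.R")

sim <- simulate_study(study_config())

for (cl in names(sim$freqs)) {
  write_tsv_commented(sim$freqs[[cl]]$values,
                      file.path(OUT, paste0("freqs_", cl, ".tsv")),
                      sprintf("simulate seed=%d", MASTER_SEED),
                      rownames_as = "family")
  for (layer in c("gene", "nmr"))
    write_tsv_commented(sim$omics[[layer]][[cl]]$X,
                        file.path(OUT, sprintf("omics_%s_%s.tsv", layer, cl)),
                        sprintf("simulate seed=%d layer=%s", MASTER_SEED,
                                layer),
                        rownames_as = "feature")
  utils::write.csv(sim$pheno[[cl]]$table,
                   file.path(OUT, paste0("pheno_", cl, ".csv")),
                   row.names = FALSE)
}
write_tsv_commented(sim$pedigree, file.path(OUT, "pedigree.tsv"),
                    "simulate: pedigree")
write_tsv_commented(sim$snp_map, file.path(OUT, "snp_map.tsv"),
                    "simulate: SNP map")
write_tsv_commented(sim$gene_map, file.path(OUT, "gene_map.tsv"),
                    "simulate: gene spans")

truth <- list(
  hubs_gene = sim$precision$gene$hubs,
  hubs_nmr = sim$precision$nmr$hubs,
  modules_gene = sim$precision$gene$modules,
  h2_gene = sim$truth$h2$gene,
  h2_nmr = sim$truth$h2$nmr,
  genetic_correlations = sim$truth$gc)
jsonlite::write_json(truth, file.path(OUT, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)
for (layer in c("gene", "nmr")) for (k in 1:2)
  write_tsv_commented(sim$precision[[layer]]$Theta[[k]],
                      file.path(OUT, sprintf("true_theta_%s_class%d.tsv",
                                             layer, k)),
                      "simulate: planted precision", rownames_as = NULL)

message(sprintf(
  "simulated %d + %d families, %d SNPs, %d gene + %d NMR features, %d traits",
  nrow(sim$freqs$class1$values), nrow(sim$freqs$class2$values),
  ncol(sim$freqs$class1$values), nrow(sim$omics$gene$class1$X),
  nrow(sim$omics$nmr$class1$X), sim$config$n_traits))
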