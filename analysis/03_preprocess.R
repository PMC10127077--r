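# Step 3 -- stratification correction per omics layer and class:
# NMR intensities are mean-centred and Pareto-scaled, then every
# feature of both layers is replaced by its residual from an OLS fit on
# the top genomic PC scores (population structure from replicated
# parents would otherwise masquerade as co-expression).

source("analysis/00_common.R")

for (cl in c("class1", "class2")) {
  pcs <- read_matrix(paste0("pcs_", cl, ".tsv"))
  for (layer in c("gene", "nmr")) {
    X <- read_matrix(sprintf("omics_%s_%s.tsv", layer, cl))
    if (layer == "nmr") X <- pareto_scale(X)
    P <- min(10, ncol(pcs))
    Xc <- regress_out_pcs(X, pcs, P = P)
    write_tsv_commented(Xc,
                        file.path(OUT, sprintf("corrected_%s_%s.tsv",
                                               layer, cl)),
                        sprintf("preprocess layer=%s pcs=%d%s", layer, P,
                                if (layer == "nmr") " pareto" else ""),
                        rownames_as = "feature")
    message(sprintf("%s/%s: %d features corrected for %d PCs",
                    cl, layer, nrow(Xc), P))
  }
}
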