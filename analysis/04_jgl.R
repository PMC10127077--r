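# Step 4 -- two-class sparse precision estimation by the fused joint
# graphical lasso with BIC model selection.  The lambda1/lambda2 grid
# here is a reduced version of the full study grids so this demo-scale
# analysis finishes in a couple of minutes; swap in
# default_penalty_grid("nmr"/"gene") for the full search.

source("analysis/00_common.R")

demo_grid <- list(lambda1 = exp(seq(log(0.05), log(20), length.out = 10)),
                  lambda2 = seq(0, 0.5, length.out = 4))

for (layer in c("gene", "nmr")) {
  Xs <- lapply(c("class1", "class2"), function(cl)
    read_matrix(sprintf("corrected_%s_%s.tsv", layer, cl)))
  gs <- jgl_grid_search(Xs, grid = demo_grid)
  write_tsv_commented(gs$surface,
                      file.path(OUT, paste0("bic_surface_", layer, ".tsv")),
                      sprintf("jgl layer=%s grid=%dx%d", layer,
                              length(demo_grid$lambda1),
                              length(demo_grid$lambda2)))
  for (k in 1:2) {
    write_tsv_commented(gs$best$Theta[[k]],
                        file.path(OUT, sprintf("theta_%s_class%d.tsv",
                                               layer, k)),
                        sprintf("jgl lambda1=%.4g lambda2=%.4g bic=%.2f",
                                gs$best$lambda1, gs$best$lambda2,
                                gs$best$bic),
                        rownames_as = "feature")
    write_tsv_commented(gs$best$partial_correlations[[k]],
                        file.path(OUT, sprintf("pcor_%s_class%d.tsv",
                                               layer, k)),
                        "jgl partial correlations",
                        rownames_as = "feature")
  }
  ec <- count_edges(gs$best$Theta)
  message(sprintf(
    "%s: selected (lambda1=%.3g, lambda2=%.3g); %d / %d edges, %d shared",
    layer, gs$best$lambda1, gs$best$lambda2,
    ec$per_class[1], ec$per_class[2], ec$shared))
}
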