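# Step 5 -- network reconstruction: adjacency from the estimated
# precision supports, Louvain modules, Kleinberg hub scores, top-5 hubs
# per module, and the conserved-hub intersection across the two
# pedigree classes.  Recovery of the planted hubs is reported against
# the ground truth written by step 1.

source("analysis/00_common.R")

truth <- jsonlite::read_json(file.path(OUT, "ground_truth.json"),
                             simplifyVector = TRUE)

for (layer in c("gene", "nmr")) {
  Theta <- lapply(1:2, function(k)
    read_matrix(sprintf("theta_%s_class%d.tsv", layer, k)))
  ns <- network_stage(structure(list(Theta = Theta), class = "jgl_fit"),
                      k_per_module = 5,
                      seed = derive_seed(MASTER_SEED, "louvain"))
  for (k in 1:2) {
    write_tsv_commented(ns$hubs[[k]],
                        file.path(OUT, sprintf("hubs_%s_class%d.tsv",
                                               layer, k)),
                        sprintf("network k_hubs=5 modularity=%.3f",
                                ns$modules[[k]]$modularity))
    write_tsv_commented(
      data.frame(feature = names(ns$modules[[k]]$membership),
                 module = as.integer(ns$modules[[k]]$membership)),
      file.path(OUT, sprintf("modules_%s_class%d.tsv", layer, k)),
      "network: Louvain membership")
  }
  write_tsv_commented(ns$conserved,
                      file.path(OUT, paste0("conserved_hubs_", layer,
                                            ".tsv")),
                      "network: conserved hubs (intersection by feature)")
  planted <- paste0(layer, truth[[paste0("hubs_", layer)]])
  message(sprintf(
    "%s: %d conserved hubs; %d / %d planted hubs among them",
    layer, nrow(ns$conserved),
    sum(planted %in% ns$conserved$feature), length(planted)))
}
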