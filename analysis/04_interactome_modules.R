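#!/usr/bin/env Rscript
# Map the replicated signatures and their overlap onto the confidence-filtered
# interactome; compute module statistics (average degree, clustering, LCC,
# betweenness hubs), randomization-based edge-enrichment p and Z, and pairwise
# module-closeness Z-scores against a degree-binned random null.

suppressMessages(library(pesignet))

inp <- "results/inputs"; sig_dir <- "results/signatures"
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260928L

net <- load_interactome(file.path(inp, "interactome.tsv"), min_confidence = 0.4)
print(net)

labels <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
sigs <- lapply(labels, function(f) {
  d <- data.table::fread(file.path(sig_dir, sprintf("signature_replicated_%s.tsv", f)))
  gene_signature(d$gene, d$direction, label = f, provenance = "replicated")
})
names(sigs) <- labels
ov <- data.table::fread(file.path(sig_dir, "signature_overlap.tsv"))
sigs$overlap <- gene_signature(ov$gene, ov$direction, label = "overlap",
                               provenance = "overlap")

stats_rows <- list()
for (f in names(sigs)) {
  mod <- build_module(sigs[[f]], net)
  st <- module_stats(mod)
  enr <- edge_enrichment_test(mod, net, n_iter = 999, seed = seed + 40L)
  cat(sprintf("%-18s mapped %3d (%.2f%%): avg degree %.2f, clustering %.2f, LCC %d, enrichment p = %.4g (Z = %.1f)\n",
              f, length(mod$mapped), mod$mapped_fraction, st$avg_degree,
              st$avg_clustering, st$lcc_nodes, enr$p, enr$z))
  data.table::fwrite(st$nodes, file.path(out, sprintf("module_nodes_%s.tsv", f)),
                     sep = "\t")
  stats_rows[[f]] <- data.frame(
    module = f, n_mapped = length(mod$mapped),
    mapped_pct = mod$mapped_fraction, n_edges = st$n_edges,
    avg_degree = st$avg_degree, avg_clustering = st$avg_clustering,
    lcc_nodes = st$lcc_nodes, lcc_edges = st$lcc_edges,
    enrichment_p = enr$p, enrichment_z = enr$z)
}
data.table::fwrite(do.call(rbind, stats_rows),
                   file.path(out, "module_stats.tsv"), sep = "\t")

# hub genes of the overlap module by betweenness
ov_nodes <- data.table::fread(file.path(out, "module_nodes_overlap.tsv"))
hubs <- head(ov_nodes[order(-ov_nodes$betweenness)], 5)
cat("\ntop overlap-module hubs by betweenness:\n")
print(hubs[, c("gene", "degree", "betweenness")])

# pairwise closeness of the four condition modules
mods <- lapply(sigs[labels], build_module, net = net)
pairs <- utils::combn(labels, 2)
rows <- lapply(seq_len(ncol(pairs)), function(j) {
  cl <- module_closeness(mods[[pairs[1, j]]], mods[[pairs[2, j]]], net,
                         n_iter = 1000, seed = seed + 41L + j)
  cat(sprintf("%s vs %s: d = %.3f, random %.3f +/- %.4f, Z = %.2f%s\n",
              pairs[1, j], pairs[2, j], cl$d_obs, cl$mu_rand, cl$sigma_rand,
              cl$z, if (cl$significantly_close) "  [close]" else ""))
  data.frame(module_a = pairs[1, j], module_b = pairs[2, j], d_obs = cl$d_obs,
             mu_rand = cl$mu_rand, sigma_rand = cl$sigma_rand, z = cl$z,
             significantly_close = cl$significantly_close)
})
data.table::fwrite(do.call(rbind, rows),
                   file.path(out, "module_closeness.tsv"), sep = "\t")
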