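#!/usr/bin/env Rscript
# Replication of the discovery signatures in the independent cohort (two-sided
# permutation p < 0.05 with direction concordance), four-way intersection with
# exclusive UpSet-style counts, and the all-conditions vs no-condition
# sensitivity contrast.

suppressMessages(library(pesignet))

inp <- "results/inputs"; de_dir <- "results/de"; out <- "results/signatures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260928L

repl <- read_study_tsv(file.path(inp, "replication_expression.tsv"),
                       file.path(inp, "replication_phenotypes.tsv"))
disc <- read_study_tsv(file.path(inp, "discovery_expression.tsv"),
                       file.path(inp, "discovery_phenotypes.tsv"))
truth <- data.table::fread(file.path(inp, "truth.tsv"))

flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
sigs <- list()
for (i in seq_along(flags)) {
  f <- flags[i]
  ds <- data.table::fread(file.path(de_dir, sprintf("signature_discovery_%s.tsv", f)))
  disc_sig <- gene_signature(ds$gene, ds$direction, label = f)
  de_rep <- permutation_pfp(repl, f, B = 100, seed = seed + 20L + i)
  sigs[[f]] <- replicate_signature(disc_sig, de_rep, alpha = 0.05)
  write_signature_tsv(sigs[[f]], file.path(out, sprintf("signature_replicated_%s.tsv", f)))
  cat(sprintf("%-18s %4d discovered -> %4d replicated (%.0f%%)\n",
              f, nrow(disc_sig), nrow(sigs[[f]]),
              100 * nrow(sigs[[f]]) / max(1, nrow(disc_sig))))
}

report <- intersect_signatures(sigs)
overlap <- report$overlap
write_signature_tsv(overlap, file.path(out, "signature_overlap.tsv"))
jsonlite::write_json(as.list(report$exclusive_counts),
                     file.path(out, "intersection_counts.json"),
                     auto_unbox = TRUE)
core <- truth$gene[rowSums(as.matrix(truth[, ..flags])) == 4]
cat(sprintf("\nfour-way overlap: %d genes (%d up); planted core recovered %d/%d\n",
            nrow(overlap), sum(overlap$direction == "up"),
            length(intersect(overlap$gene, core)), length(core)))

sens <- pesignet:::sensitivity_contrast(disc, B = 100, alpha = 0.05,
                                        seed = seed + 30L)
sf <- sensitivity_overlap(sens, overlap)
cat(sprintf("sensitivity contrast: %d DE genes; %d/%d of the overlap (%d%%)\n",
            nrow(sens), sf$n_shared, sf$n_overlap, sf$percent))
jsonlite::write_json(sf, file.path(out, "sensitivity.json"), auto_unbox = TRUE)
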