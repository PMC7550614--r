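#!/usr/bin/env Rscript
# GO-style over-representation analysis of the overlap signature against the
# expression universe, and set-level Wang semantic similarity (best-match
# average) between the PE signature and each co-condition signature.

suppressMessages(library(pesignet))

inp <- "results/inputs"; sig_dir <- "results/signatures"
out <- "results/functional"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dag <- parse_obo_subset(file.path(inp, "ontology.obo"))
ann <- as.data.frame(data.table::fread(file.path(inp, "annotations.tsv")))
truth <- data.table::fread(file.path(inp, "truth.tsv"))
universe <- truth$gene

ov <- data.table::fread(file.path(sig_dir, "signature_overlap.tsv"))
enr <- ora(ov$gene, universe, ann, dag = dag, min_term_size = 3)
data.table::fwrite(enr, file.path(out, "go_enrichment.tsv"), sep = "\t")
n_sig <- sum(enr$q < 0.05)
cat(sprintf("ORA over %d terms: %d significant at BH q < 0.05\n",
            nrow(enr), n_sig))
cat("(annotations are drawn independently of the planted signatures, so\n")
cat(" enrichment at the q < 0.05 level is expected to be absent)\n\n")

labels <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
sig_genes <- lapply(labels, function(f)
  data.table::fread(file.path(sig_dir,
                              sprintf("signature_replicated_%s.tsv", f)))$gene)
names(sig_genes) <- labels
rows <- lapply(labels[-1], function(f) {
  s <- set_sim(sig_genes$PE, sig_genes[[f]], ann, dag)
  cat(sprintf("set similarity PE vs %-18s %.3f\n", f, as.numeric(s)))
  data.frame(set_a = "PE", set_b = f, similarity = as.numeric(s))
})
data.table::fwrite(do.call(rbind, rows),
                   file.path(out, "set_similarity.tsv"), sep = "\t")
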