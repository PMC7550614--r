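#!/usr/bin/env Rscript
# Simulate the synthetic study inputs: a discovery cohort of 157 pregnancies
# with four overlapping planted condition signatures (24-gene common core), an
# independent replication cohort of the same planted truth, a
# degree-heterogeneous interactome in which the planted signatures cluster, a
# GO-like ontology with gene annotations, and a placental two-group study
# expressing 41% of the blood core. All downstream scripts read from
# results/inputs.

suppressMessages(library(pesignet))

out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260928L

spec <- cohort_spec(seed = seed)
disc <- simulate_cohort(spec)
rep_spec <- spec; rep_spec$n_samples <- 60L; rep_spec$seed <- seed + 1L
repl <- simulate_cohort(rep_spec, truth = disc$truth)

flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
planted_sets <- lapply(flags, function(f) disc$truth$gene[disc$truth[[f]]])
net <- simulate_interactome(nrow(disc$truth), "powerlaw_cluster",
                            planted_modules = planted_sets, boost = 0.12,
                            node_names = disc$truth$gene, seed = seed + 2L)
onto <- simulate_ontology(150, genes = disc$truth$gene,
                          annotations_per_gene = 3, seed = seed + 3L)
plac <- simulate_placenta(disc$truth, concordance = 0.41, n_samples = 40,
                          seed = seed + 4L)

write_study_tsv(disc$study, file.path(out, "discovery_expression.tsv"),
                file.path(out, "discovery_phenotypes.tsv"))
write_study_tsv(repl$study, file.path(out, "replication_expression.tsv"),
                file.path(out, "replication_phenotypes.tsv"))
write_study_tsv(plac$study, file.path(out, "placenta_expression.tsv"),
                file.path(out, "placenta_phenotypes.tsv"))
data.table::fwrite(disc$truth, file.path(out, "truth.tsv"), sep = "\t")
write_interactome_tsv(net, file.path(out, "interactome.tsv"))
write_obo_subset(onto$dag, file.path(out, "ontology.obo"))
data.table::fwrite(onto$annotations, file.path(out, "annotations.tsv"),
                   sep = "\t")
jsonlite::write_json(list(seed = seed, n_genes = spec$n_genes,
                          n_samples = spec$n_samples,
                          core_size = spec$core_size,
                          effect_size = spec$effect_size),
                     file.path(out, "manifest.json"), auto_unbox = TRUE)

cat(sprintf("discovery: %d genes x %d samples; core of %d genes planted in all four conditions\n",
            nrow(disc$study$values), ncol(disc$study$values), spec$core_size))
cat(sprintf("interactome: %d nodes, %d edges\n",
            igraph::vcount(net$graph), igraph::ecount(net$graph)))
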