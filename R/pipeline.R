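#' Validate and normalize a pipeline configuration
#'
#' Fills defaults for every omitted field and range-checks thresholds. The
#' configuration drives [run_pipeline()]; it may be a YAML file path or a
#' (possibly nested) list with any of the fields below.
#'
#' \describe{
#'   \item{seed}{master seed; per-stage substreams are derived from it.}
#'   \item{out_dir}{output directory; `NULL` keeps results in memory only.}
#'   \item{thresholds}{`pfp` (0.05), `replication_alpha` (0.05),
#'     `confidence` (0.4), `bh_q` (0.05), `closeness_z` (-1.65).}
#'   \item{iterations}{`B` (100 label permutations), `enrichment_n_iter`
#'     (999), `closeness_n_iter` (1000).}
#'   \item{discovery}{arguments for [cohort_spec()] (discovery cohort).}
#'   \item{replication_n_samples}{replication cohort size (60).}
#'   \item{placenta}{`concordance` (0.41), `n_samples` (40).}
#'   \item{interactome_boost}{internal edge-density boost for planted
#'     modules (0.12).}
#'   \item{ontology}{`n_terms` (150), `annotations_per_gene` (3).}
#' }
#'
#' @param config list or YAML path; `NULL` or empty means all defaults.
#' @return A normalized `PipelineConfig` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- config %||% list()
  dft <- list(
    seed = 1L, out_dir = NULL,
    thresholds = list(pfp = 0.05, replication_alpha = 0.05, confidence = 0.4,
                      bh_q = 0.05, closeness_z = -1.65),
    iterations = list(B = 100L, enrichment_n_iter = 999L,
                      closeness_n_iter = 1000L),
    discovery = list(),
    replication_n_samples = 60L,
    placenta = list(concordance = 0.41, n_samples = 40L),
    interactome_boost = 0.12,
    ontology = list(n_terms = 150L, annotations_per_gene = 3L)
  )
  cfg <- utils::modifyList(dft, config)
  th <- cfg$thresholds
  for (f in c("pfp", "replication_alpha", "bh_q"))
    if (th[[f]] <= 0 || th[[f]] >= 1)
      stop("threshold '", f, "' must lie in (0,1)")
  if (th$confidence < 0 || th$confidence >= 1)
    stop("threshold 'confidence' must lie in [0,1)")
  if (th$closeness_z >= 0) stop("threshold 'closeness_z' must be negative")
  if (cfg$iterations$B < 1) stop("iterations$B must be >= 1")
  cfg$discovery_spec <- do.call(cohort_spec, utils::modifyList(
    list(seed = stage_seed(cfg$seed, 1L)), cfg$discovery))
  class(cfg) <- "PipelineConfig"
  cfg
}

# deterministic per-stage substream seeds below 2^31
stage_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% (2^31 - 1))
}

#' Run the full synthetic signature-network workflow
#'
#' Executes, in dependency order: cohort simulation (discovery + independent
#' replication of the same planted truth), rank-product DE for the four
#' conditions, discovery calls at pfp < threshold, replication filtering at
#' two-sided permutation p < alpha with direction concordance, four-way
#' intersection, all-vs-none sensitivity contrast, interactome module
#' construction with edge-enrichment and pairwise closeness Z-scores, GO-style
#' enrichment plus set-level Wang similarity on a synthetic ontology, and
#' placental cross-tissue replication of the overlap signature. Writes TSV /
#' JSON outputs and a run manifest when `out_dir` is set.
#'
#' @param config a `PipelineConfig`, list, or YAML path (see
#'   [validate_config()]).
#' @return list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config else validate_config(config)
  flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
  man <- list(config = cfg[setdiff(names(cfg), c("discovery_spec", "out_dir"))],
              stages = list())
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(stage, ...) {
    man$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = ", ")))
  }

  ## 1. simulate
  disc <- simulate_cohort(cfg$discovery_spec)
  rep_spec <- cfg$discovery_spec
  rep_spec$n_samples <- as.integer(cfg$replication_n_samples)
  rep_spec$seed <- stage_seed(cfg$seed, 2L)
  repl <- simulate_cohort(rep_spec, truth = disc$truth)
  truth <- disc$truth
  core <- truth_core(truth)
  planted_sets <- lapply(flags, function(f) truth$gene[truth[[f]]])
  net <- simulate_interactome(n_nodes = nrow(truth),
                              model = "powerlaw_cluster",
                              planted_modules = planted_sets,
                              boost = cfg$interactome_boost,
                              node_names = truth$gene,
                              seed = stage_seed(cfg$seed, 3L))
  onto <- simulate_ontology(n_terms = cfg$ontology$n_terms,
                            genes = truth$gene,
                            annotations_per_gene = cfg$ontology$annotations_per_gene,
                            seed = stage_seed(cfg$seed, 4L))
  plac <- simulate_placenta(truth, concordance = cfg$placenta$concordance,
                            n_samples = cfg$placenta$n_samples,
                            effect_size = cfg$discovery_spec$effect_size,
                            noise_sd = cfg$discovery_spec$noise_sd,
                            seed = stage_seed(cfg$seed, 5L))
  emit("simulate", n_genes = nrow(truth), core_size = length(core),
       interactome_edges = igraph::ecount(net$graph))

  ## 2. discovery DE + calls
  de_disc <- lapply(seq_along(flags), function(i)
    permutation_pfp(disc$study, flags[i], B = cfg$iterations$B,
                    seed = stage_seed(cfg$seed, 10L + i)))
  names(de_disc) <- flags
  sigs_disc <- lapply(de_disc, call_de, pfp_threshold = cfg$thresholds$pfp)
  emit("discovery_de",
       n_called = paste(vapply(sigs_disc, nrow, integer(1)), collapse = "/"))

  ## 3. replication
  de_rep <- lapply(seq_along(flags), function(i)
    permutation_pfp(repl$study, flags[i], B = cfg$iterations$B,
                    seed = stage_seed(cfg$seed, 20L + i)))
  names(de_rep) <- flags
  sigs_rep <- lapply(flags, function(f)
    replicate_signature(sigs_disc[[f]], de_rep[[f]],
                        alpha = cfg$thresholds$replication_alpha))
  names(sigs_rep) <- flags
  emit("replication",
       n_replicated = paste(vapply(sigs_rep, nrow, integer(1)), collapse = "/"))

  ## 4. intersection
  report <- intersect_signatures(sigs_rep)
  overlap <- report$overlap
  emit("intersect", overlap_size = nrow(overlap),
       core_recovered = length(intersect(overlap$gene, core)))

  ## 5. sensitivity: all four conditions vs none
  sens <- sensitivity_contrast(disc$study, B = cfg$iterations$B,
                               alpha = cfg$thresholds$replication_alpha,
                               seed = stage_seed(cfg$seed, 30L))
  sens_frac <- if (nrow(overlap)) sensitivity_overlap(sens, overlap) else NULL
  emit("sensitivity", n_de = nrow(sens),
       percent_of_overlap = if (is.null(sens_frac)) NA else sens_frac$percent)

  ## 6. modules + enrichment + closeness
  modules <- lapply(c(sigs_rep, list(overlap = overlap)), build_module, net = net)
  stats <- lapply(modules, module_stats)
  enrich <- lapply(modules, edge_enrichment_test, net = net,
                   n_iter = cfg$iterations$enrichment_n_iter,
                   seed = stage_seed(cfg$seed, 31L))
  pairs <- utils::combn(flags, 2)
  closeness <- lapply(seq_len(ncol(pairs)), function(j)
    module_closeness(modules[[pairs[1, j]]], modules[[pairs[2, j]]], net,
                     n_iter = cfg$iterations$closeness_n_iter,
                     seed = stage_seed(cfg$seed, 40L + j)))
  emit("network",
       overlap_mapped = length(modules$overlap$mapped),
       overlap_lcc = stats$overlap$lcc_nodes,
       overlap_enrichment_p = enrich$overlap$p,
       n_close_pairs = sum(vapply(closeness, `[[`, logical(1),
                                  "significantly_close")))

  ## 7. GO enrichment and set similarity
  universe <- truth$gene
  enrichment_rows <- ora(overlap$gene, universe, onto$annotations, onto$dag)
  sig_terms <- enrichment_rows[enrichment_rows$q < cfg$thresholds$bh_q, ]
  semsim <- vapply(flags[-1], function(f)
    as.numeric(set_sim(sigs_rep[["PE"]]$gene, sigs_rep[[f]]$gene,
                       onto$annotations, onto$dag)), numeric(1))
  emit("functional", n_enriched_terms = nrow(sig_terms),
       min_set_sim = if (length(semsim)) round(min(semsim), 3) else NA)

  ## 8. cross-tissue (placenta)
  tissue <- tissue_replication(overlap, plac$study, group_flag = "PE",
                               alpha = cfg$thresholds$replication_alpha,
                               B = cfg$iterations$B,
                               seed = stage_seed(cfg$seed, 50L), net = net)
  emit("cross_tissue", n_de = tissue$n_de,
       called_fraction = tissue$called_fraction)

  res <- list(config = cfg, truth = truth, core = core,
              discovery = disc, replication = repl, interactome = net,
              ontology = onto, placenta = plac,
              de_discovery = de_disc, de_replication = de_rep,
              signatures_discovery = sigs_disc,
              signatures_replicated = sigs_rep,
              intersection = report, overlap = overlap,
              sensitivity = sens, sensitivity_fraction = sens_frac,
              modules = modules, module_stats = stats,
              enrichment = enrich, closeness = closeness,
              go_enrichment = enrichment_rows, set_similarity = semsim,
              tissue = tissue, manifest = man)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' All-conditions vs no-condition sensitivity contrast
#'
#' Restricts a cohort to the subjects positive for all four condition flags
#' and those positive for none, runs the rank-product permutation analysis on
#' that two-group contrast, and returns the genes called at two-sided
#' permutation p < `alpha`.
#'
#' @param study an `ExpressionStudy`.
#' @param B label permutations.
#' @param alpha two-sided significance level.
#' @param seed integer seed.
#' @return A `GeneSignature` labelled `"all_vs_none"`.
#' @export
sensitivity_contrast <- function(study, B = 100L, alpha = 0.05, seed = 1L) {
  ph <- study$phenotypes
  flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
  n_cond <- rowSums(as.matrix(ph[flags]))
  keep <- n_cond %in% c(0L, 4L)
  if (sum(n_cond == 4L) < 2 || sum(n_cond == 0L) < 2)
    stop("too few all-conditions or no-condition subjects for the sensitivity contrast")
  sub <- study
  sub$values <- study$values[, keep, drop = FALSE]
  sub$phenotypes <- ph[keep, , drop = FALSE]
  sub$phenotypes$all_conditions <- as.integer(n_cond[keep] == 4L)
  res <- permutation_pfp(sub, "all_conditions", B = B, seed = seed)
  p2 <- pmin(1, 2 * pmin(res$p_up, res$p_down))
  dir <- ifelse(res$p_up <= res$p_down, "up", "down")
  called <- p2 < alpha
  gene_signature(res$gene[called], dir[called], label = "all_vs_none",
                 provenance = "discovery")
}

write_pipeline_outputs <- function(res, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  write_study_tsv(res$discovery$study, p("discovery_expression.tsv"),
                  p("discovery_phenotypes.tsv"))
  write_study_tsv(res$replication$study, p("replication_expression.tsv"),
                  p("replication_phenotypes.tsv"))
  data.table::fwrite(res$truth, p("truth.tsv"), sep = "\t")
  write_interactome_tsv(res$interactome, p("interactome.tsv"))
  write_obo_subset(res$ontology$dag, p("ontology.obo"))
  data.table::fwrite(res$ontology$annotations, p("annotations.tsv"), sep = "\t")
  for (f in names(res$de_discovery))
    write_de_tsv(res$de_discovery[[f]], p(sprintf("de_discovery_%s.tsv", f)))
  for (f in names(res$signatures_replicated))
    write_signature_tsv(res$signatures_replicated[[f]],
                        p(sprintf("signature_replicated_%s.tsv", f)))
  write_signature_tsv(res$overlap, p("signature_overlap.tsv"))
  jsonlite::write_json(as.list(res$intersection$exclusive_counts),
                       p("intersection_counts.json"), auto_unbox = TRUE)
  data.table::fwrite(res$go_enrichment, p("go_enrichment.tsv"), sep = "\t")
  closeness_df <- do.call(rbind, lapply(res$closeness, function(x)
    data.frame(module_a = x$labels[1], module_b = x$labels[2],
               d_obs = x$d_obs, mu_rand = x$mu_rand, sigma_rand = x$sigma_rand,
               z = x$z, significantly_close = x$significantly_close)))
  data.table::fwrite(closeness_df, p("module_closeness.tsv"), sep = "\t")
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(out_dir)
}
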