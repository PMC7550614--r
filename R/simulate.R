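#' Specification of a synthetic maternal cohort
#'
#' Defines the design of a simulated two-group microarray-like study over four
#' overlapping maternal conditions. Baseline log2 intensities are drawn per
#' gene as mean ~ Uniform(`baseline_mean_range`) and biological SD ~
#' Uniform(`baseline_sd_range`); per-observation Gaussian measurement noise
#' with SD `noise_sd` is added, so a gene's total SD is
#' sqrt(sd_g^2 + noise_sd^2). Each condition plants `signature_sizes[c]`
#' differentially expressed genes, of which a common `core_size` genes are
#' planted in all four conditions; planted sets are disjoint outside that
#' core. Samples positive for a condition are shifted by +/- `effect_size`
#' (log2 units) at each gene planted for that condition; the sign is random
#' per gene and fixed across conditions sharing the gene.
#'
#' Default sizes mirror the discovery design (157 pregnancies; condition
#' prevalences approximately 0.30, 0.40, 0.66, 0.76 for preeclampsia, asthma,
#' excess BMI and vitamin D insufficiency), scaled to a 1000-gene universe.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples.
#' @param condition_prevalences named or ordered numeric vector of four
#'   prevalences in (0,1) for PE, asthma, excess_BMI, vitD_insufficient.
#' @param signature_sizes integer vector of four planted signature sizes.
#' @param core_size number of genes planted in all four conditions.
#' @param effect_size additive log2-scale shift (delta) for planted genes.
#' @param baseline_mean_range,baseline_sd_range log2-intensity ranges for the
#'   per-gene baseline mean and biological SD.
#' @param noise_sd per-observation measurement noise SD (log2 units).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(n_genes = 1000L,
                        n_samples = 157L,
                        condition_prevalences = c(PE = 0.30, asthma = 0.40,
                                                  excess_BMI = 0.66,
                                                  vitD_insufficient = 0.76),
                        signature_sizes = c(PE = 96L, asthma = 121L,
                                            excess_BMI = 111L,
                                            vitD_insufficient = 79L),
                        core_size = 24L,
                        effect_size = 1.0,
                        baseline_mean_range = c(4, 12),
                        baseline_sd_range = c(0.2, 0.6),
                        noise_sd = 0.5,
                        seed = 1L) {
  flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
  condition_prevalences <- stats::setNames(as.numeric(condition_prevalences), flags)
  signature_sizes <- stats::setNames(as.integer(signature_sizes), flags)
  spec <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
               condition_prevalences = condition_prevalences,
               signature_sizes = signature_sizes,
               core_size = as.integer(core_size),
               effect_size = as.numeric(effect_size),
               baseline_mean_range = as.numeric(baseline_mean_range),
               baseline_sd_range = as.numeric(baseline_sd_range),
               noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$core_size > min(spec$signature_sizes))
    stop("core_size exceeds a signature size")
  if (any(spec$condition_prevalences <= 0 | spec$condition_prevalences >= 1))
    stop("condition prevalences must lie in (0,1)")
  if (!is.finite(spec$effect_size)) stop("effect_size must be finite")
  total_exclusive <- sum(spec$signature_sizes - spec$core_size)
  if (total_exclusive + spec$core_size > spec$n_genes)
    stop("planted signatures do not fit in n_genes")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(spec)
}

#' Simulate a cohort with planted overlapping condition signatures
#'
#' Draws an expression matrix under the model described in [cohort_spec()] and
#' returns it together with the ground-truth table of planted effects. The
#' four planted gene sets intersect exactly in the declared core set; effects
#' are additive across conditions a sample is positive for.
#'
#' @param spec a `CohortSpec`.
#' @param truth optional truth table from a previous [simulate_cohort()] call;
#'   when supplied the same planted sets, directions and effect sizes are
#'   re-used (e.g. to draw an independent replication cohort of the same
#'   underlying effects) and only phenotypes and expression are redrawn.
#' @return list with `study` (an [expression_study()]) and `truth`, a
#'   data.frame with one row per gene: logical membership columns per
#'   condition, `direction` (+1/-1, NA for unplanted genes) and `effect`.
#' @export
simulate_cohort <- function(spec, truth = NULL) {
  validate_cohort_spec(spec)
  flags <- names(spec$signature_sizes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  genes <- if (is.null(truth)) sprintf("G%05d", seq_len(spec$n_genes))
           else truth$gene
  samples <- sprintf("S%03d", seq_len(spec$n_samples))

  if (is.null(truth)) {
    # planted membership: core first, then disjoint exclusive remainders
    pool <- sample(genes)
    core <- sort(pool[seq_len(spec$core_size)])
    pool <- pool[-seq_len(spec$core_size)]
    membership <- matrix(FALSE, spec$n_genes, 4L,
                         dimnames = list(genes, flags))
    membership[core, ] <- TRUE
    for (f in flags) {
      n_extra <- spec$signature_sizes[[f]] - spec$core_size
      if (n_extra > 0) {
        extra <- pool[seq_len(n_extra)]
        pool <- pool[-seq_len(n_extra)]
        membership[extra, f] <- TRUE
      }
    }
    planted <- rowSums(membership) > 0
    direction <- rep(NA_integer_, spec$n_genes)
    direction[planted] <- sample(c(-1L, 1L), sum(planted), replace = TRUE)
  } else {
    spec$n_genes <- length(genes)
    membership <- as.matrix(truth[, flags])
    rownames(membership) <- genes
    planted <- rowSums(membership) > 0
    direction <- truth$direction
  }

  # phenotypes: independent Bernoulli flags
  ph <- data.frame(sample = samples)
  for (f in flags)
    ph[[f]] <- stats::rbinom(spec$n_samples, 1L, spec$condition_prevalences[[f]])

  mu <- stats::runif(spec$n_genes, spec$baseline_mean_range[1], spec$baseline_mean_range[2])
  sd_g <- stats::runif(spec$n_genes, spec$baseline_sd_range[1], spec$baseline_sd_range[2])
  total_sd <- sqrt(sd_g^2 + spec$noise_sd^2)
  m <- mu + matrix(stats::rnorm(spec$n_genes * spec$n_samples), spec$n_genes) * total_sd
  dimnames(m) <- list(genes, samples)

  # additive planted shifts per (gene, condition)
  if (spec$effect_size != 0) {
    for (f in flags) {
      pos <- which(ph[[f]] == 1L)
      g <- which(membership[, f])
      if (length(pos) && length(g))
        m[g, pos] <- m[g, pos] + direction[g] * spec$effect_size
    }
  }

  truth <- data.frame(gene = genes, membership,
                      direction = direction,
                      effect = ifelse(planted, spec$effect_size, 0),
                      row.names = NULL, check.names = FALSE)
  list(study = expression_study(m, ph), truth = truth)
}

#' Core genes of a truth table
#'
#' Genes planted in all four conditions.
#' @param truth a truth table from [simulate_cohort()].
#' @return character vector of gene IDs.
#' @export
truth_core <- function(truth) {
  flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
  truth$gene[rowSums(as.matrix(truth[, flags])) == 4L]
}

#' Simulate an interactome with planted locally clustered modules
#'
#' Generates an undirected simple graph by either a powerlaw-cluster process
#' (preferential attachment with triad closure, yielding a heavy-tailed degree
#' distribution and non-trivial clustering) or an Erdos-Renyi model, then
#' boosts the internal edge density of each planted module: every internal
#' pair gains an edge with probability `boost` if not already present.
#' Combined confidence scores are attached per edge; edges created by the
#' boost always score above 0.4 so planted structure survives default
#' confidence filtering.
#'
#' @param n_nodes number of nodes (>= 10); node names default to `G00001`...
#' @param model `"powerlaw_cluster"` or `"erdos_renyi"`.
#' @param planted_modules list of character vectors of node names.
#' @param boost probability of adding each missing internal edge of a planted
#'   module (1 = clique).
#' @param m_attach edges per new node (powerlaw_cluster).
#' @param p_triad probability a powerlaw_cluster edge closes a triad.
#' @param p_edge edge probability (erdos_renyi).
#' @param node_names optional explicit node names.
#' @param seed integer seed.
#' @return An `Interactome` (see [load_interactome()]), unfiltered
#'   (`min_confidence = 0`).
#' @export
simulate_interactome <- function(n_nodes, model = c("powerlaw_cluster", "erdos_renyi"),
                                 planted_modules = list(), boost = 0.5,
                                 m_attach = 3L, p_triad = 0.5, p_edge = 0.01,
                                 node_names = NULL, seed = 1L) {
  model <- match.arg(model)
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nodes <- if (is.null(node_names)) sprintf("G%05d", seq_len(n_nodes)) else node_names
  stopifnot(length(nodes) == n_nodes)
  for (mod in planted_modules)
    if (!all(mod %in% nodes)) stop("planted module contains nodes absent from the graph")

  edges <- if (model == "erdos_renyi") {
    g <- igraph::sample_gnp(n_nodes, p_edge, directed = FALSE)
    igraph::as_edgelist(g, names = FALSE)
  } else {
    powerlaw_cluster_edges(n_nodes, m_attach, p_triad)
  }
  ekey <- new.env(parent = emptyenv())
  put_edge <- function(i, j) {
    if (i == j) return(FALSE)
    k <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    if (is.null(ekey[[k]])) { ekey[[k]] <- c(min(i, j), max(i, j)); TRUE } else FALSE
  }
  if (nrow(edges)) apply(edges, 1, function(e) put_edge(e[1], e[2]))
  base_keys <- ls(ekey)
  boosted <- character(0)
  idx <- stats::setNames(seq_along(nodes), nodes)
  for (mod in planted_modules) {
    ids <- sort(idx[mod])
    if (length(ids) < 2) next
    prs <- utils::combn(ids, 2)
    for (q in seq_len(ncol(prs))) {
      if (stats::runif(1) < boost && put_edge(prs[1, q], prs[2, q]))
        boosted <- c(boosted, paste0(prs[1, q], "_", prs[2, q]))
    }
  }
  keys <- ls(ekey)
  em <- t(vapply(keys, function(k) ekey[[k]], numeric(2)))
  # with an active boost, every module-internal edge counts as boosted so the
  # planted structure survives default confidence filtering
  if (boost > 0) {
    for (mod in planted_modules) {
      ids <- sort(idx[mod])
      if (length(ids) < 2) next
      prs <- utils::combn(ids, 2)
      boosted <- c(boosted, paste0(prs[1, ], "_", prs[2, ]))
    }
  }
  score <- stats::runif(length(keys), 0.15, 0.95)
  score[keys %in% boosted] <- stats::runif(sum(keys %in% boosted), 0.41, 0.99)
  df <- data.frame(geneA = nodes[em[, 1]], geneB = nodes[em[, 2]],
                   combined_score = round(score, 3))
  load_interactome(df, min_confidence = 0, all_nodes = nodes)
}

# Preferential attachment with triad closure (Holme-Kim style): each new node
# attaches m edges; the first by degree-proportional sampling, subsequent ones
# close a triad with probability p_triad (random neighbour of the previous
# target), otherwise attach preferentially again.
powerlaw_cluster_edges <- function(n, m, p_triad) {
  m <- max(1L, as.integer(m))
  repeated <- integer(0)        # degree-proportional urn
  edges <- matrix(0L, 0, 2)
  adj <- vector("list", n)
  seed_nodes <- seq_len(m + 1L)
  for (i in seed_nodes[-1]) {    # seed clique-ish chain
    edges <- rbind(edges, c(i - 1L, i))
    adj[[i - 1L]] <- c(adj[[i - 1L]], i); adj[[i]] <- c(adj[[i]], i - 1L)
    repeated <- c(repeated, i - 1L, i)
  }
  for (v in seq.int(m + 2L, n)) {
    targets <- integer(0)
    prev <- NA_integer_
    while (length(targets) < m) {
      cand <- NA_integer_
      if (!is.na(prev) && stats::runif(1) < p_triad) {
        nb <- setdiff(adj[[prev]], c(v, targets))
        if (length(nb)) cand <- nb[sample.int(length(nb), 1L)]
      }
      if (is.na(cand)) {
        cand <- repeated[sample.int(length(repeated), 1L)]
        if (cand %in% targets || cand == v) { prev <- cand; next }
      }
      targets <- c(targets, cand)
      prev <- cand
    }
    for (t in targets) {
      edges <- rbind(edges, c(v, t))
      adj[[v]] <- c(adj[[v]], t); adj[[t]] <- c(adj[[t]], v)
      repeated <- c(repeated, v, t)
    }
  }
  edges
}

#' Simulate a GO-like rooted DAG with typed edges and gene annotations
#'
#' Builds a single-rooted acyclic ontology: term `T0001` is the root; every
#' other term receives one primary parent among shallower terms (keeping depth
#' at most `max_depth`), typed `part_of` with probability `part_of_fraction`
#' and `is_a` otherwise; a fraction of terms gain a second parent, keeping the
#' structure a DAG. Each gene is annotated to exactly `annotations_per_gene`
#' distinct non-root terms.
#'
#' @param n_terms number of terms (>= 2), including the root.
#' @param max_depth maximum term depth (root = 0); `1` yields a star.
#' @param part_of_fraction probability an edge is typed `part_of`.
#' @param genes character vector of gene IDs to annotate.
#' @param annotations_per_gene annotations per gene (exact).
#' @param second_parent_prob probability a non-root term gains a second parent.
#' @param seed integer seed.
#' @return list with `dag` (an `OntologyDag`, see [parse_obo_subset()]) and
#'   `annotations` (data.frame gene, term).
#' @export
simulate_ontology <- function(n_terms, max_depth = 4L, part_of_fraction = 0.2,
                              genes = character(0), annotations_per_gene = 3L,
                              second_parent_prob = 0.15, seed = 1L) {
  if (n_terms < 2) stop("n_terms must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ids <- sprintf("T%04d", seq_len(n_terms))
  depth <- c(0L, rep(NA_integer_, n_terms - 1L))
  child <- parent <- relation <- character(0)
  for (i in seq.int(2L, n_terms)) {
    cands <- which(!is.na(depth) & depth < max_depth & seq_len(n_terms) < i)
    p <- cands[sample.int(length(cands), 1L)]
    depth[i] <- depth[p] + 1L
    child <- c(child, ids[i]); parent <- c(parent, ids[p])
    relation <- c(relation, if (stats::runif(1) < part_of_fraction) "part_of" else "is_a")
    if (stats::runif(1) < second_parent_prob) {
      c2 <- setdiff(which(!is.na(depth) & depth < depth[i] & seq_len(n_terms) < i), p)
      if (length(c2)) {
        p2 <- c2[sample.int(length(c2), 1L)]
        child <- c(child, ids[i]); parent <- c(parent, ids[p2])
        relation <- c(relation, if (stats::runif(1) < part_of_fraction) "part_of" else "is_a")
      }
    }
  }
  terms <- data.frame(id = ids, name = paste("synthetic term", ids),
                      namespace = "synthetic_process")
  dag <- ontology_dag(terms, data.frame(child = child, parent = parent,
                                        relation = relation))
  ann <- NULL
  if (length(genes)) {
    k <- min(as.integer(annotations_per_gene), n_terms - 1L)
    ann <- do.call(rbind, lapply(genes, function(g)
      data.frame(gene = g, term = sample(ids[-1L], k))))
  }
  list(dag = dag, annotations = ann)
}

#' Simulate a placental replication study of a blood core signature
#'
#' Emulates testing a blood-derived overlapping signature in a second tissue:
#' a two-group (PE vs control analog) matrix over the same gene universe in
#' which a `concordance` fraction of the blood core signature is planted with
#' the same direction as in blood; all other genes are null. The planted
#' count is `round(concordance * core size)` under round-half-even.
#'
#' @param blood_truth truth table from [simulate_cohort()].
#' @param concordance fraction of the blood core planted in placenta, in
#'   \[0,1\].
#' @param n_samples total samples; groups are balanced (cases = ceiling half).
#' @param effect_size log2 shift for planted genes.
#' @param baseline_mean_range,baseline_sd_range,noise_sd as in [cohort_spec()].
#' @param seed integer seed.
#' @return list with `study` (PE flag marks the case group; other flags 0) and
#'   `truth` (gene, planted, direction).
#' @export
simulate_placenta <- function(blood_truth, concordance, n_samples = 40L,
                              effect_size = 1.0,
                              baseline_mean_range = c(4, 12),
                              baseline_sd_range = c(0.2, 0.6),
                              noise_sd = 0.5, seed = 1L) {
  if (concordance < 0 || concordance > 1) stop("concordance must lie in [0,1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genes <- blood_truth$gene
  core <- truth_core(blood_truth)
  n_plant <- round(concordance * length(core))   # round-half-even
  planted <- if (n_plant > 0) sort(sample(core, n_plant)) else character(0)

  n_case <- ceiling(n_samples / 2)
  samples <- sprintf("P%03d", seq_len(n_samples))
  ph <- data.frame(sample = samples,
                   PE = rep(c(1L, 0L), c(n_case, n_samples - n_case)),
                   asthma = 0L, excess_BMI = 0L, vitD_insufficient = 0L)
  n_genes <- length(genes)
  mu <- stats::runif(n_genes, baseline_mean_range[1], baseline_mean_range[2])
  sd_g <- stats::runif(n_genes, baseline_sd_range[1], baseline_sd_range[2])
  total_sd <- sqrt(sd_g^2 + noise_sd^2)
  m <- mu + matrix(stats::rnorm(n_genes * n_samples), n_genes) * total_sd
  dimnames(m) <- list(genes, samples)
  dir_all <- stats::setNames(blood_truth$direction, blood_truth$gene)
  if (length(planted)) {
    gi <- match(planted, genes)
    m[gi, seq_len(n_case)] <- m[gi, seq_len(n_case)] + dir_all[planted] * effect_size
  }
  truth <- data.frame(gene = genes,
                      planted = genes %in% planted,
                      direction = ifelse(genes %in% planted, dir_all[genes], NA_integer_))
  list(study = expression_study(m, ph), truth = truth)
}

# RNG scope helpers: save/restore the global seed so generators are seeded
# without disturbing the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
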