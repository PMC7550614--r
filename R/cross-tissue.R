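#' Signature genes expressed in every sample of a study
#'
#' Retains signature genes that are present in the expression matrix and have
#' a non-missing value in every sample.
#'
#' @param signature a `GeneSignature` or character vector of genes.
#' @param study an `ExpressionStudy` (or a matrix that may contain NAs).
#' @return character vector of gene ids.
#' @export
expressed_in_all <- function(signature, study) {
  genes <- if (is.character(signature)) unique(signature) else unique(signature$gene)
  m <- if (is.matrix(study)) study else study$values
  if (!length(m)) stop("study is empty")
  present <- intersect(genes, rownames(m))
  present[rowSums(is.na(m[present, , drop = FALSE])) == 0L]
}

#' Test a blood-derived signature in a second tissue
#'
#' Runs the rank-product permutation analysis on the full tissue matrix,
#' restricts to the signature genes expressed in all samples, calls genes at
#' two-sided permutation p < `alpha` (`min(1, 2*min(p_up, p_down))`), then
#' maps the called subset back onto the interactome and computes submodule
#' statistics and LCC size. Rank statistics are genome-wide: DE is computed on
#' the whole matrix and intersected with the signature afterwards.
#'
#' @param signature a `GeneSignature` (the blood overlap signature).
#' @param study tissue `ExpressionStudy`.
#' @param group_flag condition flag defining the two groups (e.g. `PE`).
#' @param alpha two-sided significance level.
#' @param B permutations for [permutation_pfp()].
#' @param seed integer seed.
#' @param net optional `Interactome` for re-mapping; `NULL` skips mapping.
#' @param use_pfp call genes on pfp instead of permutation p (default FALSE).
#' @param scheme a [pairing_scheme()].
#' @return A `TissueReplicationReport` list: `n_signature`,
#'   `n_expressed_in_all`, `n_de`, `de` (gene, direction, p), `called_fraction`
#'   (percent), and if `net` given `module_stats`, `lcc_nodes`, `n_mapped`.
#' @export
tissue_replication <- function(signature, study, group_flag = "PE",
                               alpha = 0.05, B = 100L, seed = 1L, net = NULL,
                               use_pfp = FALSE, scheme = pairing_scheme()) {
  genes <- unique(signature$gene)
  expressed <- expressed_in_all(signature, study)
  de_res <- permutation_pfp(study, group_flag, scheme = scheme, B = B, seed = seed)
  idx <- match(expressed, de_res$gene)
  if (use_pfp) {
    stat <- pmin(de_res$pfp_up[idx], de_res$pfp_down[idx])
  } else {
    stat <- pmin(1, 2 * pmin(de_res$p_up[idx], de_res$p_down[idx]))
  }
  dir <- ifelse(de_res$p_up[idx] < de_res$p_down[idx], "up",
         ifelse(de_res$p_down[idx] < de_res$p_up[idx], "down",
                ifelse(de_res$mean_log2_diff[idx] >= 0, "up", "down")))
  called <- stat < alpha
  de <- data.frame(gene = expressed[called], direction = dir[called],
                   p = stat[called], row.names = NULL)
  rep <- list(n_signature = length(genes),
              n_expressed_in_all = length(expressed),
              n_de = nrow(de), de = de,
              called_fraction = round(100 * nrow(de) / length(genes), 2))
  if (!is.null(net) && nrow(de)) {
    sub_sig <- gene_signature(de$gene, de$direction,
                              label = paste0(attr(signature, "label"), "_tissue"),
                              provenance = "placenta")
    mod <- build_module(sub_sig, net)
    rep$n_mapped <- length(mod$mapped)
    if (length(mod$mapped)) {
      st <- module_stats(mod)
      rep$module_stats <- st
      rep$lcc_nodes <- st$lcc_nodes
    }
  }
  structure(rep, class = "TissueReplicationReport")
}

#' @export
print.TissueReplicationReport <- function(x, ...) {
  cat(sprintf("TissueReplication: %d/%d signature genes DE (%.1f%%), %d expressed in all samples\n",
              x$n_de, x$n_signature, x$called_fraction, x$n_expressed_in_all))
  if (!is.null(x$lcc_nodes))
    cat(sprintf("  mapped: %d, LCC: %d nodes\n", x$n_mapped, x$lcc_nodes))
  invisible(x)
}

#' Translate gene identifiers through a mapping table
#'
#' One-to-one translation of identifiers (e.g. probe to Entrez). Sources with
#' no mapping are reported unmapped. When several sources collapse onto one
#' target, the source with the highest mean expression is kept if an
#' expression matrix is supplied, else the first occurrence.
#'
#' @param genes character vector of source identifiers.
#' @param mapping data.frame with two columns (source, target).
#' @param expression optional matrix rownamed by source identifiers, used to
#'   resolve many-to-one collisions.
#' @return list with `mapped` (data.frame source, target), `unmapped`
#'   (character), `n_collisions`.
#' @export
map_ids <- function(genes, mapping, expression = NULL) {
  if (!nrow(mapping)) stop("empty mapping table")
  names(mapping)[1:2] <- c("source", "target")
  hit <- mapping[match(genes, mapping$source), ]
  unmapped <- genes[is.na(hit$target)]
  ok <- !is.na(hit$target)
  df <- data.frame(source = genes[ok], target = hit$target[ok])
  n_coll <- 0L
  if (anyDuplicated(df$target)) {
    score <- if (!is.null(expression)) {
      rowMeans(expression)[df$source]
    } else -seq_len(nrow(df))  # first occurrence wins
    ord <- order(df$target, -score)
    dfo <- df[ord, ]
    keep <- !duplicated(dfo$target)
    n_coll <- sum(!keep)
    df <- dfo[keep, ]
    df <- df[order(match(df$source, genes)), ]
  }
  list(mapped = df, unmapped = unmapped, n_collisions = n_coll)
}
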