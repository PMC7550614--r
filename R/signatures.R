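#' Construct a GeneSignature
#'
#' A directed gene set: each entry is a gene with direction `up` or `down`,
#' carrying a condition label and a provenance tag.
#'
#' @param gene character vector of gene IDs (no duplicates).
#' @param direction character vector, `"up"` or `"down"`, recycled if length 1.
#' @param label condition name.
#' @param provenance one of `discovery`, `replicated`, `overlap`, `placenta`.
#' @return A `GeneSignature` data.frame.
#' @export
gene_signature <- function(gene, direction = "up", label = "signature",
                           provenance = c("discovery", "replicated",
                                          "overlap", "placenta")) {
  provenance <- match.arg(provenance)
  if (length(direction) == 1L) direction <- rep(direction, length(gene))
  stopifnot(length(gene) == length(direction))
  if (anyDuplicated(gene)) stop("a gene appears more than once in the signature")
  if (!all(direction %in% c("up", "down"))) stop("direction must be up/down")
  structure(data.frame(gene = as.character(gene),
                       direction = as.character(direction),
                       stringsAsFactors = FALSE),
            label = label, provenance = provenance,
            class = c("GeneSignature", "data.frame"))
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s' (%s): %d genes (%d up)\n",
              attr(x, "label"), attr(x, "provenance"),
              nrow(x), sum(x$direction == "up")))
  invisible(x)
}

#' Replicate a discovery signature against an independent cohort
#'
#' Retains discovery genes whose replication two-sided permutation p-value
#' `min(1, 2 * min(p_up, p_down))` falls below `alpha` and (by default) whose
#' replication direction matches discovery. The replication direction is the
#' side with the smaller one-tailed p, breaking ties by the sign of the mean
#' log2 difference. Discovery genes absent from the replication result are
#' dropped and counted.
#'
#' @param discovery a `GeneSignature`.
#' @param replication a `DEResult` from the replication cohort.
#' @param alpha two-sided significance level in (0,1).
#' @param require_direction require direction concordance (default TRUE).
#' @return A `GeneSignature` with provenance `"replicated"` and attributes
#'   `n_missing`, `n_discordant`.
#' @export
replicate_signature <- function(discovery, replication, alpha = 0.05,
                                require_direction = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  idx <- match(discovery$gene, replication$gene)
  missing <- is.na(idx)
  disc <- discovery[!missing, , drop = FALSE]
  idx <- idx[!missing]
  p2 <- pmin(1, 2 * pmin(replication$p_up[idx], replication$p_down[idx]))
  rep_dir <- ifelse(replication$p_up[idx] < replication$p_down[idx], "up",
             ifelse(replication$p_down[idx] < replication$p_up[idx], "down",
                    ifelse(replication$mean_log2_diff[idx] >= 0, "up", "down")))
  keep <- p2 < alpha
  discordant <- keep & rep_dir != disc$direction
  if (require_direction) keep <- keep & rep_dir == disc$direction
  out <- gene_signature(disc$gene[keep], disc$direction[keep],
                        label = attr(discovery, "label"),
                        provenance = "replicated")
  attr(out, "n_missing") <- sum(missing)
  attr(out, "n_discordant") <- sum(discordant)
  out
}

#' Four-way signature intersection with exclusive (UpSet-style) counts
#'
#' Membership is by gene symbol; direction is ignored for membership. The
#' direction of overlap genes is taken from the first (PE) signature and
#' checked for concordance across the other signatures; discordant genes are
#' counted in the `n_discordant` attribute.
#'
#' @param signatures list of exactly four `GeneSignature`s with distinct
#'   labels.
#' @return An `IntersectionReport` list: `exclusive_counts` (named by
#'   `+`-joined label subsets), `overlap` (a `GeneSignature`, provenance
#'   `"overlap"`), `union_size`.
#' @export
intersect_signatures <- function(signatures) {
  if (length(signatures) != 4L) stop("exactly four signatures required")
  labels <- vapply(signatures, attr, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate signature labels")
  sets <- lapply(signatures, function(s) unique(s$gene))
  names(sets) <- labels
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(r) paste(labels[r], collapse = "+"))
  subsets <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, paste, collapse = "+")))
  counts <- stats::setNames(integer(length(subsets)), subsets)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  ov_genes <- universe[rowSums(member) == 4L]
  pe_sig <- signatures[[1L]]
  dir_pe <- pe_sig$direction[match(ov_genes, pe_sig$gene)]
  n_disc <- 0L
  for (s in signatures[-1L]) {
    d <- s$direction[match(ov_genes, s$gene)]
    n_disc <- n_disc + sum(d != dir_pe, na.rm = TRUE)
  }
  overlap <- gene_signature(ov_genes, dir_pe, label = "overlap",
                            provenance = "overlap")
  attr(overlap, "n_discordant") <- n_disc
  structure(list(exclusive_counts = counts, overlap = overlap,
                 union_size = length(universe)),
            class = "IntersectionReport")
}

#' @export
print.IntersectionReport <- function(x, ...) {
  cat("IntersectionReport: union of", x$union_size, "genes;",
      nrow(x$overlap), "in the four-way overlap\n")
  nz <- x$exclusive_counts[x$exclusive_counts > 0]
  print(sort(nz, decreasing = TRUE))
  invisible(x)
}

#' Sensitivity-analysis overlap fraction
#'
#' Fraction of an overlap signature recovered by an independent all-conditions
#' vs no-conditions contrast, as a percentage rounded to the nearest integer.
#'
#' @param all_vs_none a `GeneSignature` from the all-vs-none contrast.
#' @param overlap the overlapping `GeneSignature`.
#' @return list with `n_shared`, `n_overlap`, `percent`.
#' @export
sensitivity_overlap <- function(all_vs_none, overlap) {
  if (!nrow(overlap)) stop("overlap signature is empty")
  shared <- intersect(unique(all_vs_none$gene), unique(overlap$gene))
  list(n_shared = length(shared), n_overlap = nrow(overlap),
       percent = round(100 * length(shared) / nrow(overlap)))
}

#' Write a GeneSignature as a 2-column TSV (gene, direction)
#' @param sig a `GeneSignature`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_signature_tsv <- function(sig, path) {
  data.table::fwrite(as.data.frame(sig), path, sep = "\t")
  invisible(path)
}
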