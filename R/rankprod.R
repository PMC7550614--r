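#' Pairing scheme for unpaired two-class rank products
#'
#' The rank product for an unpaired design is computed over case-control
#' sample pairings. With `mode = "all_pairs"` every one of the n1*n2 pairings
#' is used when their number does not exceed `n_pairs_cap`; beyond the cap (or
#' with `mode = "sampled"`) a seeded random subset of `n_pairs_cap` pairings
#' is drawn.
#'
#' @param mode `"all_pairs"` or `"sampled"`.
#' @param n_pairs_cap maximum number of pairings (>= 1).
#' @param seed integer seed used whenever pairings are sampled.
#' @return A `PairingScheme` list.
#' @export
pairing_scheme <- function(mode = c("all_pairs", "sampled"),
                           n_pairs_cap = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  if (n_pairs_cap < 1) stop("n_pairs_cap must be >= 1")
  structure(list(mode = mode, n_pairs_cap = as.integer(n_pairs_cap),
                 seed = as.integer(seed)), class = "PairingScheme")
}

make_pairings <- function(n_case, n_control, scheme) {
  all_n <- n_case * n_control
  pairs <- cbind(case = rep(seq_len(n_case), times = n_control),
                 control = rep(seq_len(n_control), each = n_case))
  if (scheme$mode == "all_pairs" && all_n <= scheme$n_pairs_cap) return(pairs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scheme$seed)
  pairs[sample.int(all_n, min(scheme$n_pairs_cap, all_n)), , drop = FALSE]
}

#' Residualize expression on known covariates
#'
#' Replaces each gene's values by residuals from the least-squares projection
#' onto the named covariates plus an intercept. A stand-in for heterogeneity
#' adjustment when the nuisance structure is known.
#'
#' @param study an `ExpressionStudy`.
#' @param covariates character vector of phenotype-table column names; empty
#'   means no-op.
#' @return An `ExpressionStudy` of identical shape.
#' @export
residualize <- function(study, covariates = character(0)) {
  if (!length(covariates)) return(study)
  ph <- study$phenotypes
  miss <- setdiff(covariates, names(ph))
  if (length(miss)) stop("covariates not found: ", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(ph[covariates]))
  storage.mode(X) <- "double"
  if (any(apply(X[, -1, drop = FALSE], 2, stats::sd) == 0))
    stop("constant covariate supplied")
  qrX <- qr(X)
  res <- t(qr.resid(qrX, t(study$values)))
  dimnames(res) <- dimnames(study$values)
  out <- study
  out$values <- res
  out
}

# Columnwise ranks (average ties) of a genes x K matrix, fast path via
# data.table's radix ranking.
col_ranks <- function(m) {
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m)))
    out[, j] <- data.table::frankv(m[, j], ties.method = "average")
  out
}

#' Fold-change rank matrix over case-control pairings
#'
#' For each of K case-control pairings, per-gene log2 differences (case minus
#' control) are ranked so that rank 1 is the most upregulated gene for the
#' `"up"` analysis and the most downregulated for `"down"`. Ties receive
#' average ranks.
#'
#' @param study an `ExpressionStudy`.
#' @param condition condition flag naming the case group.
#' @param scheme a [pairing_scheme()].
#' @param direction `"up"` or `"down"`.
#' @return genes x K numeric rank matrix.
#' @export
fold_change_ranks <- function(study, condition, scheme = pairing_scheme(),
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  grp <- condition_groups(study, condition)
  if (!length(grp$case) || !length(grp$control))
    stop("condition '", condition, "' has an empty class")
  pr <- make_pairings(length(grp$case), length(grp$control), scheme)
  d <- study$values[, grp$case[pr[, "case"]], drop = FALSE] -
       study$values[, grp$control[pr[, "control"]], drop = FALSE]
  colnames(d) <- NULL
  if (direction == "up") d <- -d
  col_ranks(d)
}

#' Rank product of a rank matrix
#'
#' Geometric mean of ranks per gene, computed in log space:
#' RP_g = (prod_k r_gk)^(1/K).
#'
#' @param rank_matrix genes x K matrix of ranks in \[1, n_genes\].
#' @return numeric vector of per-gene rank products.
#' @export
rank_product <- function(rank_matrix) {
  if (!length(rank_matrix)) stop("empty rank matrix")
  rank_matrix <- as.matrix(rank_matrix)
  if (any(rank_matrix < 1)) stop("ranks must be >= 1")
  exp(rowMeans(log(rank_matrix)))
}

# RP for both directions at once via the compiled core (one sort per pairing;
# with average ties the down-ranks are n + 1 - up-ranks).
rp_both <- function(values, case_idx, control_idx, pairs) {
  rp_engine(values, as.integer(case_idx), as.integer(control_idx),
            cbind(as.integer(pairs[, "case"]), as.integer(pairs[, "control"])))
}

#' Rank-product permutation analysis with pfp estimates
#'
#' Runs the full two-class unpaired rank-product analysis for one condition:
#' observed RP per gene under the up and down orderings, permutation p-values
#' pooled over genes, and the percentage of false prediction (pfp), an
#' FDR-like quantity: the expected number of false positives at a gene's RP
#' cutoff divided by the gene's rank position.
#'
#' `p_g = (1 + #\{permuted RP <= RP_g over all genes and permutations\}) /
#' (1 + B * n_genes)` (add-one smoothing, never exactly zero);
#' `pfp_g = (#\{permuted RP <= RP_g\} / B) / rank(RP_g)`. pfp is reported raw
#' (it may exceed 1) in `pfp_up`/`pfp_down` and capped at 1 in
#' `pfp_up_capped`/`pfp_down_capped`.
#'
#' @param study an `ExpressionStudy`.
#' @param condition condition flag naming the case group.
#' @param scheme a [pairing_scheme()].
#' @param B number of label permutations (>= 1).
#' @param seed integer seed for permutations (and sampled pairings).
#' @return A `DEResult` data.frame (gene, RP/rank/p/pfp per direction,
#'   `mean_log2_diff`), with attributes `K`, `B`, `condition`.
#' @export
permutation_pfp <- function(study, condition, scheme = pairing_scheme(),
                            B = 100L, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  grp <- condition_groups(study, condition)
  n1 <- length(grp$case); n2 <- length(grp$control)
  if (!n1 || !n2) stop("condition '", condition, "' has an empty class")
  if (n1 < 2 && n2 < 2) warning("both classes have fewer than 2 samples")
  n_genes <- nrow(study$values)
  if (as.double(B) * n_genes > 2^31 - 1) stop("B * n_genes too large")
  pairs <- make_pairings(n1, n2, scheme)
  K <- nrow(pairs)

  obs <- rp_both(study$values, grp$case, grp$control, pairs)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  all_idx <- c(grp$case, grp$control)
  perm_up <- perm_dn <- matrix(0, n_genes, B)
  for (b in seq_len(B)) {
    lab <- sample(all_idx)
    rb <- rp_both(study$values, lab[seq_len(n1)], lab[n1 + seq_len(n2)], pairs)
    perm_up[, b] <- rb$rp_up
    perm_dn[, b] <- rb$rp_down
  }
  pool_tail <- function(obs_rp, perm) {
    sp <- sort(perm)
    cnt <- findInterval(obs_rp, sp)        # permuted RP <= observed
    r <- rank(obs_rp, ties.method = "average")
    list(p = (1 + cnt) / (1 + length(sp)),
         pfp = (cnt / B) / r,
         rank = r)
  }
  up <- pool_tail(obs$rp_up, perm_up)
  dn <- pool_tail(obs$rp_down, perm_dn)
  mean_diff <- rowMeans(study$values[, grp$case, drop = FALSE]) -
               rowMeans(study$values[, grp$control, drop = FALSE])
  res <- data.frame(gene = rownames(study$values),
                    RP_up = obs$rp_up, rank_up = up$rank,
                    p_up = up$p, pfp_up = up$pfp,
                    pfp_up_capped = pmin(up$pfp, 1),
                    RP_down = obs$rp_down, rank_down = dn$rank,
                    p_down = dn$p, pfp_down = dn$pfp,
                    pfp_down_capped = pmin(dn$pfp, 1),
                    mean_log2_diff = mean_diff, row.names = NULL)
  attr(res, "K") <- K
  attr(res, "B") <- as.integer(B)
  attr(res, "condition") <- condition
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Call differentially expressed genes from a DEResult
#'
#' A gene enters the signature as `up` when `pfp_up` falls below the threshold
#' and `down` when `pfp_down` does; genes meeting both (pathological) are
#' excluded and counted in the `n_both_excluded` attribute.
#'
#' @param result a `DEResult`.
#' @param pfp_threshold pfp cutoff (default 0.05).
#' @param label signature label; defaults to the result's condition.
#' @return A `GeneSignature` (see [gene_signature()]) with provenance
#'   `"discovery"`.
#' @export
call_de <- function(result, pfp_threshold = 0.05, label = NULL) {
  up <- result$pfp_up < pfp_threshold
  dn <- result$pfp_down < pfp_threshold
  both <- up & dn
  gene <- c(result$gene[up & !both], result$gene[dn & !both])
  direction <- c(rep("up", sum(up & !both)), rep("down", sum(dn & !both)))
  sig <- gene_signature(gene, direction,
                        label = label %||% attr(result, "condition"),
                        provenance = "discovery")
  attr(sig, "n_both_excluded") <- sum(both)
  sig
}

#' Write a DEResult as TSV
#' @param result a `DEResult`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_de_tsv <- function(result, path) {
  data.table::fwrite(as.data.frame(result), path, sep = "\t")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
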