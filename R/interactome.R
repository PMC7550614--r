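#' Load a confidence-filtered interactome
#'
#' Builds an undirected simple protein-protein interaction graph from a
#' three-column edge table (geneA, geneB, combined_score). Edges with score
#' at or below `min_confidence` are dropped (strictly greater is retained,
#' matching the "combined score > 0.4" convention of STRING exports), reversed
#' duplicates are merged keeping the maximum score, and self-loops removed.
#'
#' @param edges data.frame/path to a TSV with columns geneA, geneB,
#'   combined_score.
#' @param min_confidence confidence threshold (default 0.4).
#' @param all_nodes optional character vector of nodes to retain even if
#'   isolated after filtering.
#' @return An `Interactome`: list with `graph` (igraph, vertex attribute
#'   `name`, edge attribute `score`), `min_confidence`, and a log of dropped
#'   record counts.
#' @export
load_interactome <- function(edges, min_confidence = 0.4, all_nodes = NULL) {
  if (is.character(edges) && length(edges) == 1L)
    edges <- as.data.frame(data.table::fread(edges, sep = "\t"))
  if (ncol(edges) < 3) stop("edge table needs three columns (geneA, geneB, score)")
  names(edges)[1:3] <- c("geneA", "geneB", "combined_score")
  score <- suppressWarnings(as.numeric(edges$combined_score))
  bad <- which(is.na(score) | is.na(edges$geneA) | is.na(edges$geneB))
  if (length(bad))
    stop("malformed edge record at line ", bad[1])
  n_in <- nrow(edges)
  keep <- score > min_confidence
  edges <- edges[keep, ]; score <- score[keep]
  self <- edges$geneA == edges$geneB
  n_self <- sum(self)
  edges <- edges[!self, ]; score <- score[!self]
  a <- pmin(edges$geneA, edges$geneB)
  b <- pmax(edges$geneA, edges$geneB)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -score)           # max score first within duplicates
  first <- !duplicated(key[o])
  sel <- o[first]
  dt <- data.frame(a = a[sel], b = b[sel], score = score[sel])
  nodes <- unique(c(dt$a, dt$b, all_nodes))
  g <- igraph::graph_from_data_frame(dt, directed = FALSE, vertices = nodes)
  structure(list(graph = g, min_confidence = min_confidence,
                 log = list(n_input = n_in,
                            n_below_confidence = n_in - sum(keep),
                            n_self_loops = n_self,
                            n_duplicates = sum(keep) - n_self - nrow(dt)),
                 cache = new.env(parent = emptyenv())),
            class = "Interactome")
}

#' @export
print.Interactome <- function(x, ...) {
  cat(sprintf("Interactome: %d nodes, %d edges (score > %.2f)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$min_confidence))
  invisible(x)
}

#' Nodes of an interactome
#' @param net an `Interactome`.
#' @return character vector of gene identifiers.
#' @export
interactome_nodes <- function(net) igraph::V(net$graph)$name

#' Write an interactome as a 3-column TSV
#' @param net an `Interactome`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_interactome_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  data.table::fwrite(data.table::data.table(geneA = el[, 1], geneB = el[, 2],
                                            combined_score = igraph::E(net$graph)$score),
                     path, sep = "\t")
  invisible(path)
}

#' Map a gene signature onto the interactome
#'
#' @param signature a `GeneSignature` (or character vector of genes).
#' @param net an `Interactome`.
#' @return A `Module`: list with `label`, `mapped`, `unmapped`, `subgraph`
#'   (induced igraph), `mapped_fraction` (percent, 2 d.p.).
#' @export
build_module <- function(signature, net) {
  genes <- if (is.character(signature)) unique(signature) else unique(signature$gene)
  label <- if (is.character(signature)) "module" else attr(signature, "label")
  if (!length(genes)) stop("signature is empty")
  nodes <- interactome_nodes(net)
  mapped <- intersect(genes, nodes)
  unmapped <- setdiff(genes, nodes)
  if (!length(mapped))
    warning("no signature gene maps onto the interactome; empty module")
  sub <- igraph::induced_subgraph(net$graph, mapped)
  structure(list(label = label, mapped = mapped, unmapped = unmapped,
                 subgraph = sub,
                 mapped_fraction = round(100 * length(mapped) / length(genes), 2)),
            class = "Module")
}

#' @export
print.Module <- function(x, ...) {
  cat(sprintf("Module '%s': %d/%d genes mapped (%.2f%%), %d internal edges\n",
              x$label, length(x$mapped), length(x$mapped) + length(x$unmapped),
              x$mapped_fraction, igraph::ecount(x$subgraph)))
  invisible(x)
}

#' Module network statistics
#'
#' Internal average degree (2E/N), mean local clustering coefficient
#' (2*triangles / (deg*(deg-1)), 0 for degree < 2), largest-connected-component
#' node and edge counts, and per-node degree and betweenness (Brandes,
#' normalized by (N-1)(N-2)/2), all computed on the module's induced subgraph.
#'
#' @param m a `Module`.
#' @return A `ModuleStats` list: `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_clustering`, `lcc_nodes`, `lcc_edges`, and a per-node data.frame
#'   `nodes` (gene, degree, clustering, betweenness, in_lcc).
#' @export
module_stats <- function(m) {
  g <- m$subgraph
  n <- igraph::vcount(g)
  if (!n) stop("module is empty")
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  btw <- if (n > 2) igraph::betweenness(g, directed = FALSE, normalized = TRUE)
         else rep(0, n)
  comp <- igraph::components(g)
  lcc_id <- lcc_component_id(comp, igraph::V(g)$name)
  in_lcc <- comp$membership == lcc_id
  lcc_edges <- igraph::ecount(igraph::induced_subgraph(g, which(in_lcc)))
  structure(list(n_nodes = n, n_edges = e,
                 avg_degree = 2 * e / n,
                 avg_clustering = mean(cc),
                 lcc_nodes = sum(in_lcc), lcc_edges = lcc_edges,
                 nodes = data.frame(gene = igraph::V(g)$name, degree = deg,
                                    clustering = cc, betweenness = btw,
                                    in_lcc = in_lcc, row.names = NULL)),
            class = "ModuleStats")
}

# largest component; ties broken by the lexicographically smallest member name
lcc_component_id <- function(comp, names) {
  best <- which(comp$csize == max(comp$csize))
  if (length(best) == 1L) return(best)
  mins <- vapply(best, function(k) min(names[comp$membership == k]), character(1))
  best[order(mins)][1L]
}

#' Largest connected component of a module
#'
#' @param m a `Module`.
#' @return A `Module` restricted to the LCC (size ties broken by the
#'   lexicographically smallest member gene).
#' @export
largest_connected_component <- function(m) {
  g <- m$subgraph
  if (!igraph::vcount(g)) stop("module is empty")
  comp <- igraph::components(g)
  keep <- comp$membership == lcc_component_id(comp, igraph::V(g)$name)
  out <- m
  out$label <- paste0(m$label, "_LCC")
  out$mapped <- igraph::V(g)$name[keep]
  out$subgraph <- igraph::induced_subgraph(g, which(keep))
  out$mapped_fraction <- round(100 * sum(keep) /
                               (length(m$mapped) + length(m$unmapped)), 2)
  out
}

# ---- degree-binned null sampling -------------------------------------------

# Nodes are grouped by interactome degree; consecutive degree groups are merged
# until each bin holds at least min_bin_size nodes (the last bin is merged
# backwards), standard practice for degree-preserving set randomization.
degree_bins <- function(net, min_bin_size = 100L) {
  key <- paste0("bins_", min_bin_size)
  if (!is.null(net$cache[[key]])) return(net$cache[[key]])
  deg <- igraph::degree(net$graph)
  ord <- order(deg, igraph::V(net$graph)$name)
  degs <- deg[ord]
  bin_of <- integer(length(degs))
  b <- 1L; count <- 0L; i <- 1L
  while (i <= length(degs)) {
    d <- degs[i]
    j <- i
    while (j <= length(degs) && degs[j] == d) j <- j + 1L
    bin_of[i:(j - 1L)] <- b
    count <- count + (j - i)
    if (count >= min_bin_size) { b <- b + 1L; count <- 0L }
    i <- j
  }
  if (count > 0L && b > 1L) bin_of[bin_of == b] <- b - 1L  # merge short tail
  res <- list(node_bin = stats::setNames(bin_of[order(ord)],
                                         igraph::V(net$graph)$name),
              members = split(ord, bin_of))  # vertex indices per bin
  net$cache[[key]] <- res
  res
}

# Sample a random node set matching the degree-bin profile of `vids`
# (vertex indices); uniform sampling when degree_binned = FALSE.
sample_matched_set <- function(net, vids, degree_binned = TRUE,
                               min_bin_size = 100L) {
  nv <- igraph::vcount(net$graph)
  if (!degree_binned) return(sample.int(nv, length(vids)))
  bins <- degree_bins(net, min_bin_size)
  node_bin <- bins$node_bin[vids]
  out <- integer(0)
  for (b in unique(node_bin)) {
    k <- sum(node_bin == b)
    mem <- bins$members[[as.character(b)]]
    out <- c(out, mem[sample.int(length(mem), k)])
  }
  out
}

#' Randomization test for module edge enrichment
#'
#' Compares the module's induced edge count against random node sets of
#' identical size drawn from the interactome (degree-binned by default, so the
#' null preserves the module's degree profile). Empirical p uses add-one
#' smoothing: `(1 + #\{null >= observed\}) / (1 + n_iter)`.
#'
#' @param m a `Module`.
#' @param net the `Interactome` it was mapped onto.
#' @param n_iter number of random sets (>= 100).
#' @param seed integer seed.
#' @param degree_binned sample from degree-matched bins (default TRUE).
#' @param min_bin_size minimum nodes per degree bin.
#' @return list with `observed_edges`, `null_mean`, `null_sd`, `p`, `z`,
#'   `n_iter`.
#' @export
edge_enrichment_test <- function(m, net, n_iter = 10000L, seed = 1L,
                                 degree_binned = TRUE, min_bin_size = 100L) {
  if (n_iter < 100) stop("n_iter must be >= 100")
  if (length(m$mapped) > igraph::vcount(net$graph))
    stop("module larger than the network")
  obs <- igraph::ecount(m$subgraph)
  vids <- match(m$mapped, interactome_nodes(net))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_edges <- vapply(seq_len(n_iter), function(i) {
    s <- sample_matched_set(net, vids, degree_binned, min_bin_size)
    igraph::ecount(igraph::induced_subgraph(net$graph, s))
  }, numeric(1))
  mu <- mean(null_edges); sdv <- stats::sd(null_edges)
  list(observed_edges = obs, null_mean = mu, null_sd = sdv,
       p = (1 + sum(null_edges >= obs)) / (1 + n_iter),
       z = if (sdv > 0) (obs - mu) / sdv else NA_real_,
       n_iter = n_iter)
}

# Mean cross-set shortest-path distance on the full interactome. `dist_rows`
# is an optional precomputed distance matrix subset provider.
cross_distance <- function(net, va, vb, convention = c("all_pairs", "closest")) {
  convention <- match.arg(convention)
  D <- interactome_distances(net)[va, vb, drop = FALSE]
  finite <- is.finite(D)
  if (!any(finite)) stop("no reachable cross pair between the modules")
  if (convention == "all_pairs") {
    list(d = mean(D[finite]), unreachable = mean(!finite))
  } else {
    row_min <- apply(D, 1, function(r) if (any(is.finite(r))) min(r[is.finite(r)]) else NA)
    col_min <- apply(D, 2, function(r) if (any(is.finite(r))) min(r[is.finite(r)]) else NA)
    mins <- c(row_min, col_min)
    list(d = mean(mins, na.rm = TRUE), unreachable = mean(!finite))
  }
}

# Full unweighted distance matrix, cached on the interactome.
interactome_distances <- function(net) {
  if (is.null(net$cache$dist)) {
    nv <- igraph::vcount(net$graph)
    if (nv > 6000) stop("interactome too large to cache a full distance matrix")
    net$cache$dist <- igraph::distances(net$graph, weights = NA)
  }
  net$cache$dist
}

#' Closeness of two modules in the interactome
#'
#' Observed inter-module distance (default: mean shortest-path length over all
#' cross pairs, genes shared by both modules contributing distance 0;
#' unreachable pairs excluded and their fraction reported) compared against
#' `n_iter` degree-binned random node-set pairs of matching sizes. Modules
#' closer than expected by chance give negative Z; Z < -1.65 corresponds to
#' one-sided p < 0.05 ("significantly close").
#'
#' @param a,b `Module`s mapped onto `net`.
#' @param net the `Interactome`.
#' @param n_iter number of random pairs (>= 100).
#' @param seed integer seed.
#' @param convention `"all_pairs"` (mean over all cross pairs) or `"closest"`
#'   (symmetrized mean over per-node minimum distances).
#' @param degree_binned degree-matched null sampling (default TRUE).
#' @param min_bin_size minimum nodes per degree bin.
#' @return A `ClosenessResult` list: `labels`, `d_obs`, `mu_rand`,
#'   `sigma_rand`, `z`, `n_iter`, `unreachable_fraction`, `significantly_close`.
#' @export
module_closeness <- function(a, b, net, n_iter = 1000L, seed = 1L,
                             convention = c("all_pairs", "closest"),
                             degree_binned = TRUE, min_bin_size = 100L) {
  convention <- match.arg(convention)
  if (n_iter < 100) stop("n_iter must be >= 100")
  if (!length(a$mapped) || !length(b$mapped))
    stop("both modules must map at least one gene")
  nodes <- interactome_nodes(net)
  va <- match(a$mapped, nodes); vb <- match(b$mapped, nodes)
  obs <- cross_distance(net, va, vb, convention)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_d <- vapply(seq_len(n_iter), function(i) {
    ra <- sample_matched_set(net, va, degree_binned, min_bin_size)
    rb <- sample_matched_set(net, vb, degree_binned, min_bin_size)
    cross_distance(net, ra, rb, convention)$d
  }, numeric(1))
  mu <- mean(null_d); sdv <- stats::sd(null_d)
  z <- if (sdv > 0) (obs$d - mu) / sdv else NA_real_
  structure(list(labels = c(a$label, b$label), d_obs = obs$d,
                 mu_rand = mu, sigma_rand = sdv, z = z, n_iter = n_iter,
                 unreachable_fraction = obs$unreachable,
                 significantly_close = isTRUE(z < -1.65)),
            class = "ClosenessResult")
}

#' @export
print.ClosenessResult <- function(x, ...) {
  cat(sprintf("Closeness %s vs %s: d = %.3f, random %.3f +/- %.4f, Z = %.2f%s\n",
              x$labels[1], x$labels[2], x$d_obs, x$mu_rand, x$sigma_rand, x$z,
              if (x$significantly_close) " (significantly close)" else ""))
  invisible(x)
}
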