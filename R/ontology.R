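#' Construct an OntologyDag
#'
#' A rooted acyclic DAG of ontology terms with typed child-to-parent edges
#' (`is_a` or `part_of`). Acyclicity and reachability of a root are enforced.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @return An `OntologyDag` list with `terms`, `edges`, `roots`, and a
#'   parent-list index.
#' @export
ontology_dag <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  if (anyDuplicated(terms$id)) stop("duplicate term ids")
  dangling <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(dangling))
    stop("edge references unknown term: ", dangling[1])
  if (!all(edges$relation %in% c("is_a", "part_of")))
    stop("edge relations must be is_a or part_of")
  # cycle check by Kahn's algorithm on child -> parent edges
  n <- nrow(terms)
  idx <- stats::setNames(seq_len(n), terms$id)
  out_deg <- tabulate(idx[edges$child], n)       # edges leaving each child
  parents_of <- split(seq_len(nrow(edges)), edges$child)
  children_edges <- split(seq_len(nrow(edges)), edges$parent)
  active_out <- out_deg
  queue <- which(active_out == 0L)               # roots first
  seen <- 0L
  edge_child_idx <- idx[edges$child]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (e in children_edges[[terms$id[v]]]) {
      c_i <- edge_child_idx[e]
      active_out[c_i] <- active_out[c_i] - 1L
      if (active_out[c_i] == 0L) queue <- c(queue, c_i)
    }
  }
  if (seen < n) {
    cyc <- terms$id[active_out > 0L]
    stop("ontology contains a cycle involving: ", paste(cyc, collapse = ", "))
  }
  roots <- terms$id[out_deg == 0L]
  if (!length(roots)) stop("ontology has no root")
  structure(list(terms = terms, edges = edges, roots = roots,
                 parent_edges = parents_of), class = "OntologyDag")
}

#' @export
print.OntologyDag <- function(x, ...) {
  cat(sprintf("OntologyDag: %d terms, %d edges, root(s): %s\n",
              nrow(x$terms), nrow(x$edges), paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Parse a minimal OBO subset
#'
#' Reads `[Term]` stanzas consuming `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of` and `is_obsolete` lines; obsolete terms are
#' skipped; cycles and dangling parents are rejected.
#'
#' @param file path to an OBO file.
#' @return An `OntologyDag`.
#' @export
parse_obo_subset <- function(file) {
  lines <- readLines(file)
  terms <- list(); edges <- list()
  cur <- NULL; in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur) || isTRUE(cur$obsolete) || is.null(cur$id)) return(NULL)
    cur
  }
  store <- list()
  for (ln in c(trimws(lines), "[flush]")) {
    if (grepl("^\\[", ln)) {
      t <- flush(cur)
      if (!is.null(t)) store[[length(store) + 1L]] <- t
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term) list(parents = character(0), rels = character(0)) else NULL
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:")) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, p); cur$rels <- c(cur$rels, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      p <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      cur$parents <- c(cur$parents, p); cur$rels <- c(cur$rels, "part_of")
    } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
  }
  if (!length(store)) stop("no [Term] stanzas found")
  terms <- data.frame(id = vapply(store, `[[`, character(1), "id"),
                      name = vapply(store, function(t) t$name %||% "", character(1)),
                      namespace = vapply(store, function(t)
                        t$namespace %||% "default", character(1)))
  edges <- do.call(rbind, lapply(store, function(t)
    if (length(t$parents))
      data.frame(child = t$id, parent = t$parents, relation = t$rels)
    else NULL))
  if (is.null(edges))
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0))
  ontology_dag(terms, edges)
}

#' Write an OntologyDag as minimal OBO
#' @param dag an `OntologyDag`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_obo_subset <- function(dag, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i])), con)
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a")
        writeLines(paste0("is_a: ", e$parent[j]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
    }
  }
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each ontology term with at least `min_term_size` annotated genes in the
#' universe, tests over-representation of the signature in the term's gene set
#' with the hypergeometric upper tail `P(X >= k)`, then adjusts across tested
#' terms by Benjamini-Hochberg. Annotations are propagated to ancestor terms
#' (a gene annotated to a term is annotated to all its ancestors).
#'
#' @param signature character vector of genes (must be within `universe`).
#' @param universe character vector of background genes.
#' @param annotations data.frame (gene, term).
#' @param dag an `OntologyDag` used to propagate annotations; `NULL` to use
#'   direct annotations only.
#' @param min_term_size minimum universe annotation count per tested term.
#' @return data.frame (term, k, n, K, N, p, q) sorted by q then p.
#' @export
ora <- function(signature, universe, annotations, dag = NULL,
                min_term_size = 3L) {
  if (!length(universe)) stop("empty universe")
  if (!all(signature %in% universe))
    stop("signature genes must be contained in the universe")
  ann <- annotations[annotations$gene %in% universe, c("gene", "term")]
  if (!is.null(dag)) {
    anc <- ancestors_table(dag)
    if (!is.null(anc)) {
      extra <- merge(ann, anc, by.x = "term", by.y = "term")
      ann <- unique(rbind(ann, data.frame(gene = extra$gene, term = extra$ancestor)))
    }
  }
  ann <- unique(ann)
  term_genes <- split(ann$gene, ann$term)
  term_genes <- term_genes[lengths(term_genes) >= min_term_size]
  if (!length(term_genes))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0)))
  N <- length(unique(universe)); n <- length(unique(signature))
  K <- lengths(term_genes)
  k <- vapply(term_genes, function(g) length(intersect(g, signature)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = names(term_genes), k = k, n = n, K = K, N = N,
                    p = p, q = q, row.names = NULL)
  out[order(out$q, out$p, out$term), ]
}

# all (term, ancestor) pairs, ancestors excluding the term itself
ancestors_table <- function(dag) {
  parent_map <- split(dag$edges$parent, dag$edges$child)
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- parent_map[[t]]
    res <- if (is.null(ps)) character(0)
           else unique(c(ps, unlist(lapply(ps, anc))))
    memo[[t]] <- res
    res
  }
  do.call(rbind, lapply(dag$terms$id, function(t) {
    a <- anc(t)
    if (length(a)) data.frame(term = t, ancestor = a) else NULL
  }))
}

#' Semantic-similarity configuration (Wang method)
#'
#' @param w_is_a,w_part_of semantic contribution factors in (0,1) for the two
#'   edge types; defaults are the established Wang-method constants.
#' @return A `SemSimConfig` list.
#' @export
semsim_config <- function(w_is_a = 0.8, w_part_of = 0.6) {
  if (w_is_a <= 0 || w_is_a >= 1 || w_part_of <= 0 || w_part_of >= 1)
    stop("contribution factors must lie in (0,1)")
  structure(list(w_is_a = w_is_a, w_part_of = w_part_of, combine = "BMA"),
            class = "SemSimConfig")
}

#' Wang S-values of a term's ancestor closure
#'
#' S(term) = 1; walking up the DAG, each ancestor t takes
#' `S(t) = max over child edges c->t within the closure of w_relation * S(c)`.
#' The semantic value SV(term) is the sum of S over the closure.
#'
#' @param term term id.
#' @param dag an `OntologyDag`.
#' @param cfg a [semsim_config()].
#' @return named numeric vector of S-values over `term` and its ancestors,
#'   with attribute `SV`.
#' @export
wang_svalues <- function(term, dag, cfg = semsim_config()) {
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  w <- c(is_a = cfg$w_is_a, part_of = cfg$w_part_of)
  parent_rows <- split(seq_len(nrow(dag$edges)), dag$edges$child)
  S <- stats::setNames(1, term)
  frontier <- term
  # breadth-first relaxation; each pass propagates max-product weights upward
  while (length(frontier)) {
    nxt <- character(0)
    for (t in frontier) {
      for (e in parent_rows[[t]]) {
        p <- dag$edges$parent[e]
        val <- w[[dag$edges$relation[e]]] * S[[t]]
        if (is.na(S[p]) || val > S[[p]]) {
          S[p] <- val
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  attr(S, "SV") <- sum(S)
  S
}

#' Wang semantic similarity of two terms
#'
#' `sim(a,b) = sum over shared closure terms of (S_a(t) + S_b(t)) /
#' (SV(a) + SV(b))`.
#'
#' @param a,b term ids (same namespace).
#' @param dag an `OntologyDag`.
#' @param cfg a [semsim_config()].
#' @return similarity in \[0,1\].
#' @export
term_sim <- function(a, b, dag, cfg = semsim_config()) {
  ns <- stats::setNames(dag$terms$namespace, dag$terms$id)
  if (!a %in% dag$terms$id || !b %in% dag$terms$id) stop("unknown term")
  if (ns[[a]] != ns[[b]]) stop("cross-namespace term comparison")
  Sa <- wang_svalues(a, dag, cfg)
  Sb <- wang_svalues(b, dag, cfg)
  common <- intersect(names(Sa), names(Sb))
  if (!length(common)) return(0)
  sum(Sa[common] + Sb[common]) / (attr(Sa, "SV") + attr(Sb, "SV"))
}

# best-match-average of a similarity matrix: (sum of row maxima + sum of
# column maxima) / (nrow + ncol)
bma <- function(m) {
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (nrow(m) + ncol(m))
}

#' Wang similarity between two genes (BMA over annotated terms)
#'
#' Computes the term-pair similarity matrix over the two genes' annotations
#' and combines it by best-match-average. When annotations span several
#' namespaces, similarity is computed within each namespace shared by both
#' genes and combined by maximum.
#'
#' @param g1,g2 gene ids.
#' @param annotations data.frame (gene, term).
#' @param dag an `OntologyDag`.
#' @param cfg a [semsim_config()].
#' @return similarity in \[0,1\], or `NA` if either gene is unannotated.
#' @export
gene_sim <- function(g1, g2, annotations, dag, cfg = semsim_config()) {
  ns <- stats::setNames(dag$terms$namespace, dag$terms$id)
  t1 <- unique(annotations$term[annotations$gene == g1])
  t2 <- unique(annotations$term[annotations$gene == g2])
  if (!length(t1) || !length(t2)) return(NA_real_)
  shared_ns <- intersect(unique(ns[t1]), unique(ns[t2]))
  if (!length(shared_ns)) return(NA_real_)
  max(vapply(shared_ns, function(nsp) {
    a <- t1[ns[t1] == nsp]; b <- t2[ns[t2] == nsp]
    m <- outer(a, b, Vectorize(function(x, y) term_sim(x, y, dag, cfg)))
    m <- matrix(m, length(a), length(b))
    bma(m)
  }, numeric(1)))
}

#' Wang similarity between two gene sets (BMA over gene pairs)
#'
#' @param setA,setB character vectors of genes (each must contain at least one
#'   annotated gene; unannotated genes are excluded and counted).
#' @param annotations data.frame (gene, term).
#' @param dag an `OntologyDag`.
#' @param cfg a [semsim_config()].
#' @return similarity in \[0,1\] with attribute `n_unannotated`.
#' @export
set_sim <- function(setA, setB, annotations, dag, cfg = semsim_config()) {
  annotated <- unique(annotations$gene)
  a <- intersect(unique(setA), annotated)
  b <- intersect(unique(setB), annotated)
  n_un <- (length(unique(setA)) - length(a)) + (length(unique(setB)) - length(b))
  if (!length(a) || !length(b)) stop("a set contains no annotated gene")
  m <- matrix(NA_real_, length(a), length(b))
  for (i in seq_along(a)) for (j in seq_along(b))
    m[i, j] <- gene_sim(a[i], b[j], annotations, dag, cfg)
  if (anyNA(m)) m[is.na(m)] <- 0
  out <- bma(m)
  attr(out, "n_unannotated") <- n_un
  out
}
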