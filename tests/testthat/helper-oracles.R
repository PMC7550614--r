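# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (igraph, phyper, fisher.test, the compiled rank core)
# that the implementation relies on.

# small balanced two-group study with optional planted shift on some genes
toy_study <- function(n_genes = 10, n_case = 3, n_control = 3,
                      shift_genes = integer(0), shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  m <- matrix(rnorm(n_genes * n, mean = 8, sd = sd), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  m[shift_genes, seq_len(n_case)] <- m[shift_genes, seq_len(n_case)] + shift
  ph <- data.frame(sample = colnames(m),
                   PE = rep(c(1L, 0L), c(n_case, n_control)),
                   asthma = 0L, excess_BMI = 0L, vitD_insufficient = 0L)
  expression_study(m, ph)
}

# plain-R rank product over all case-control pairings (no compiled code)
rp_oracle <- function(values, case_idx, control_idx, direction = "up") {
  K <- length(case_idx) * length(control_idx)
  ranks <- matrix(0, nrow(values), K)
  k <- 0
  for (i in case_idx) for (j in control_idx) {
    k <- k + 1
    d <- values[, i] - values[, j]
    ranks[, k] <- if (direction == "up") rank(-d) else rank(d)
  }
  exp(rowMeans(log(ranks)))
}

# exhaustive pooled permutation p over all choose(n, n_case) labellings
exhaustive_pooled_p <- function(values, n_case, direction = "up") {
  n <- ncol(values)
  combos <- combn(n, n_case)
  obs <- rp_oracle(values, seq_len(n_case), seq.int(n_case + 1, n), direction)
  pool <- unlist(lapply(seq_len(ncol(combos)), function(ci) {
    cs <- combos[, ci]
    rp_oracle(values, cs, setdiff(seq_len(n), cs), direction)
  }))
  vapply(obs, function(r) mean(pool <= r), numeric(1))
}

# Floyd-Warshall distances and shortest-path counts from an adjacency matrix
fw_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  # path counts by DP over increasing distance
  cnt <- matrix(0, n, n); diag(cnt) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      pred <- which(adj[, v] == 1 & d[s, ] == d[s, v] - 1)
      cnt[s, v] <- sum(cnt[s, pred])
    }
  }
  list(d = d, cnt = cnt)
}

# normalized betweenness by exhaustive path counting
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  fp <- fw_paths(adj)
  b <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
      if (s == v || t == v || !is.finite(fp$d[s, t])) next
      if (is.finite(fp$d[s, v]) && is.finite(fp$d[v, t]) &&
          fp$d[s, v] + fp$d[v, t] == fp$d[s, t])
        tot <- tot + fp$cnt[s, v] * fp$cnt[v, t] / fp$cnt[s, t]
    }
    b[v] <- tot
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

# two-sided Fisher p by enumerating all tables with the observed margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hypergeometric upper tail by exhaustive enumeration of draws
hyper_tail_oracle <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # treat 1..K as the annotated genes
  mean(hits >= k)
}

# Wang S-value oracle: max over all directed paths term -> ancestor of the
# product of edge weights (w_is_a / w_part_of), by exhaustive path search
wang_oracle <- function(term, dag, w_is_a = 0.8, w_part_of = 0.6) {
  w <- c(is_a = w_is_a, part_of = w_part_of)
  S <- new.env(parent = emptyenv())
  assign(term, 1, S)
  walk <- function(t, val) {
    rows <- which(dag$edges$child == t)
    for (r in rows) {
      p <- dag$edges$parent[r]
      v <- val * w[[dag$edges$relation[r]]]
      cur <- if (exists(p, S)) get(p, S) else -Inf
      if (v > cur) assign(p, v, S)
      walk(p, v)
    }
  }
  walk(term, 1)
  vals <- mget(ls(S), S)
  stats::setNames(as.numeric(vals), names(vals))
}

# tiny deterministic interactome from an explicit edge list
edge_net <- function(edges, score = 0.9, min_confidence = 0.4, all_nodes = NULL) {
  df <- data.frame(geneA = edges[, 1], geneB = edges[, 2],
                   combined_score = score)
  load_interactome(df, min_confidence = min_confidence, all_nodes = all_nodes)
}
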