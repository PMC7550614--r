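chain_dag <- function() {
  # A is_a B is_a root
  ontology_dag(data.frame(id = c("root", "B", "A"), name = "t",
                          namespace = "bp"),
               data.frame(child = c("A", "B"), parent = c("B", "root"),
                          relation = "is_a"))
}

sibling_dag <- function() {
  ontology_dag(data.frame(id = c("root", "A", "B"), name = "t",
                          namespace = "bp"),
               data.frame(child = c("A", "B"), parent = "root",
                          relation = "is_a"))
}

test_that("OBO subset parsing builds typed DAGs and rejects cycles", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: T1", "name: root", "namespace: bp", "",
               "[Term]", "id: T2", "name: a", "namespace: bp", "is_a: T1 ! root",
               "",
               "[Term]", "id: T3", "name: b", "namespace: bp",
               "relationship: part_of T1", "",
               "[Term]", "id: T4", "name: dead", "is_obsolete: true",
               "is_a: T1"), obo)
  dag <- parse_obo_subset(obo)
  expect_equal(nrow(dag$terms), 3)     # obsolete term skipped
  expect_equal(nrow(dag$edges), 2)
  expect_equal(dag$edges$relation[dag$edges$child == "T3"], "part_of")
  expect_equal(dag$roots, "T1")

  cyc <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "is_a: B", "",
               "[Term]", "id: B", "name: b", "is_a: A"), cyc)
  expect_error(parse_obo_subset(cyc), "cycle")
  dang <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "is_a: MISSING"), dang)
  expect_error(parse_obo_subset(dang), "unknown term")
})

test_that("OBO write/parse round-trips a simulated ontology", {
  out <- simulate_ontology(25, part_of_fraction = 0.4, seed = 3)
  f <- tempfile(fileext = ".obo")
  write_obo_subset(out$dag, f)
  back <- parse_obo_subset(f)
  expect_setequal(back$terms$id, out$dag$terms$id)
  ek <- function(d) sort(paste(d$edges$child, d$edges$parent, d$edges$relation))
  expect_identical(ek(back), ek(out$dag))
})

test_that("Wang S-values match hand recursions and the path-product oracle", {
  S <- wang_svalues("A", chain_dag())
  expect_equal(S[["A"]], 1)
  expect_equal(S[["B"]], 0.8)
  expect_equal(S[["root"]], 0.64)
  expect_equal(attr(S, "SV"), 2.44)

  dagp <- ontology_dag(data.frame(id = c("root", "A"), name = "t",
                                  namespace = "bp"),
                       data.frame(child = "A", parent = "root",
                                  relation = "part_of"))
  expect_equal(wang_svalues("A", dagp)[["root"]], 0.6)
  expect_error(wang_svalues("nope", chain_dag()), "unknown term")

  # brute-force max-over-paths oracle on random simulated DAGs (<= 15 terms)
  for (s in 1:15) {
    out <- simulate_ontology(sample(5:15, 1), part_of_fraction = 0.3,
                             second_parent_prob = 0.4, seed = s)
    term <- sample(out$dag$terms$id[-1], 1)
    S_imp <- wang_svalues(term, out$dag)
    S_or <- wang_oracle(term, out$dag)
    expect_setequal(names(S_imp), names(S_or))
    expect_equal(S_imp[names(S_or)], S_or, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("term similarity reproduces hand values and identity", {
  expect_equal(term_sim("A", "A", sibling_dag()), 1)
  expect_equal(term_sim("A", "B", sibling_dag()), (0.8 + 0.8) / (1.8 + 1.8),
               tolerance = 1e-12)
  # disjoint roots share no ancestors
  dag2 <- ontology_dag(data.frame(id = c("r1", "r2", "x", "y"), name = "t",
                                  namespace = "bp"),
                       data.frame(child = c("x", "y"), parent = c("r1", "r2"),
                                  relation = "is_a"))
  expect_equal(term_sim("x", "y", dag2), 0)
  dag3 <- ontology_dag(data.frame(id = c("r", "x"), name = "t",
                                  namespace = c("bp", "mf")),
                       data.frame(child = "x", parent = "r",
                                  relation = "is_a")[0, ])
  expect_error(term_sim("r", "x", dag3), "namespace")
})

test_that("similarity is symmetric and bounded at every level", {
  set.seed(4)
  out <- simulate_ontology(20, genes = sprintf("g%d", 1:8),
                           annotations_per_gene = 3, seed = 6)
  dag <- out$dag; ann <- out$annotations
  ids <- dag$terms$id
  for (i in 1:10) {
    a <- sample(ids, 1); b <- sample(ids, 1)
    s1 <- term_sim(a, b, dag); s2 <- term_sim(b, a, dag)
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_gte(s1, 0); expect_lte(s1, 1 + 1e-12)
  }
  expect_equal(gene_sim("g1", "g1", ann, dag), 1)
  g12 <- gene_sim("g1", "g2", ann, dag)
  expect_equal(g12, gene_sim("g2", "g1", ann, dag), tolerance = 1e-12)
  expect_true(g12 >= 0 && g12 <= 1)
  s <- set_sim(c("g1", "g2", "g3"), c("g1", "g2", "g3"), ann, dag)
  expect_equal(as.numeric(s), 1, tolerance = 1e-12)
})

test_that("BMA combination matches the hand-worked matrices", {
  # matrix [[0.9, 0.7], [0.5, 0.3]] -> 0.75
  expect_equal(pesignet:::bma(matrix(c(0.9, 0.5, 0.7, 0.3), 2)), 0.75)
  # 1x1 matrix
  expect_equal(pesignet:::bma(matrix(0.42, 1, 1)), 0.42)
  # 2x1 gene-similarity case: sims (0.8, 0.4) -> (0.8 + 0.4 + 0.8)/3
  expect_equal(pesignet:::bma(matrix(c(0.8, 0.4), 2, 1)), 2 / 3,
               tolerance = 1e-12)
})

test_that("singleton set similarity reduces to gene similarity", {
  out <- simulate_ontology(20, genes = sprintf("g%d", 1:6),
                           annotations_per_gene = 2, seed = 9)
  expect_equal(as.numeric(set_sim("g1", "g2", out$annotations, out$dag)),
               gene_sim("g1", "g2", out$annotations, out$dag),
               tolerance = 1e-12)
  expect_error(set_sim("zz", "g1", out$annotations, out$dag), "no annotated")
})

test_that("gene sets on one branch are more similar than sets on disjoint branches", {
  # two deep branches under the root
  terms <- data.frame(id = c("root", "L1", "L2", "L3", "R1", "R2", "R3"),
                      name = "t", namespace = "bp")
  edges <- data.frame(child = c("L1", "L2", "L3", "R1", "R2", "R3"),
                      parent = c("root", "L1", "L2", "root", "R1", "R2"),
                      relation = "is_a")
  dag <- ontology_dag(terms, edges)
  for (s in 1:5) {
    set.seed(s)
    annL <- data.frame(gene = rep(c("a1", "a2", "b1", "b2"), each = 2),
                       term = c(sample(c("L1", "L2", "L3"), 4, TRUE),
                                sample(c("L1", "L2", "L3"), 4, TRUE)))
    annR <- annL
    annR$term[annR$gene %in% c("b1", "b2")] <-
      sample(c("R1", "R2", "R3"), 4, TRUE)
    same <- as.numeric(set_sim(c("a1", "a2"), c("b1", "b2"), annL, dag))
    diff <- as.numeric(set_sim(c("a1", "a2"), c("b1", "b2"), annR, dag))
    expect_gt(same, diff)
  }
})

test_that("hypergeometric ORA matches hand values and exhaustive enumeration", {
  # worked example: N=20, K=5, n=5, k=5
  ann <- data.frame(gene = sprintf("g%02d", 1:5), term = "T1")
  universe <- sprintf("g%02d", 1:20)
  res <- ora(sprintf("g%02d", 1:5), universe, ann, min_term_size = 3)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # k=0 -> p=1
  res0 <- ora(sprintf("g%02d", 10:14), universe, ann, min_term_size = 3)
  expect_equal(res0$p, 1)
  expect_error(ora("g01", character(0), ann), "empty universe")
  expect_error(ora("zz", universe, ann), "contained")

  # exhaustive enumeration on universes <= 15 genes
  set.seed(8)
  for (i in 1:10) {
    N <- sample(8:15, 1); K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    univ <- sprintf("u%02d", 1:N)
    annK <- data.frame(gene = univ[1:K], term = "TT")
    sig <- sample(univ, n)
    k <- sum(sig %in% univ[1:K])
    r <- ora(sig, univ, annK, min_term_size = min(3, K))
    expect_equal(r$p[r$term == "TT"], hyper_tail_oracle(N, K, n, k),
                 tolerance = 1e-10)
  }
})

test_that("ORA q-values are BH-adjusted and monotone in sorted raw p", {
  # hand BH: raw p (0.01, 0.02, 0.03) over three terms -> q all 0.03
  q_hand <- pmin(1, rev(cummin(rev(sort(c(0.01, 0.02, 0.03)) * 3 / 1:3))))
  expect_equal(q_hand, rep(0.03, 3))
  set.seed(2)
  for (i in 1:5) {
    out <- simulate_ontology(25, genes = sprintf("g%02d", 1:30),
                             annotations_per_gene = 4, seed = i)
    res <- ora(sprintf("g%02d", sample(30, 10)), sprintf("g%02d", 1:30),
               out$annotations, min_term_size = 3)
    res <- res[order(res$p), ]
    # q computed by an independent hand BH on the raw p-vector
    m <- nrow(res)
    q_or <- pmin(1, rev(cummin(rev(res$p * m / seq_len(m)))))
    expect_equal(res$q, q_or, tolerance = 1e-12)
    expect_true(all(diff(res$q) >= -1e-12))
  }
})

test_that("annotations propagate to ancestors in ORA", {
  dag <- chain_dag()
  ann <- data.frame(gene = c("g1", "g2", "g3"), term = "A")
  universe <- sprintf("g%d", 1:10)
  res <- ora(c("g1", "g2", "g3"), universe, ann, dag = dag, min_term_size = 3)
  # A, B and root all carry the same three genes after propagation
  expect_setequal(res$term, c("A", "B", "root"))
  expect_true(all(res$k == 3))
})
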