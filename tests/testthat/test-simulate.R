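test_that("cohort simulation is reproducible and honors the overlap structure", {
  spec <- cohort_spec(n_genes = 400, n_samples = 60,
                      signature_sizes = c(40, 50, 45, 35), core_size = 20,
                      seed = 7)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$study$values, b$study$values)
  expect_identical(a$truth, b$truth)

  flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
  sets <- lapply(flags, function(f) a$truth$gene[a$truth[[f]]])
  expect_equal(lengths(sets), c(40, 50, 45, 35))
  core <- Reduce(intersect, sets)
  expect_setequal(core, truth_core(a$truth))
  expect_length(core, 20)
  # disjoint outside the core: pairwise intersections equal the core exactly
  for (i in 1:3) for (j in (i + 1):4)
    expect_setequal(intersect(sets[[i]], sets[[j]]), core)
  # direction fixed across conditions sharing a gene (single column in truth)
  expect_true(all(a$truth$direction[a$truth$gene %in% core] %in% c(-1L, 1L)))
})

test_that("null effect size yields near-zero group differences", {
  spec <- cohort_spec(n_genes = 300, n_samples = 120, effect_size = 0,
                      signature_sizes = c(30, 30, 30, 30), core_size = 10,
                      seed = 3)
  sim <- simulate_cohort(spec)
  grp <- condition_groups(sim$study, "PE")
  d <- rowMeans(sim$study$values[, grp$case]) -
       rowMeans(sim$study$values[, grp$control])
  expect_lt(mean(abs(d)), 0.2)    # Monte-Carlo scale for ~0.7 SD noise
  expect_lt(abs(mean(d)), 0.05)
})

test_that("planted core genes show the specified effect (group-mean oracle)", {
  spec <- cohort_spec(n_genes = 1000, n_samples = 200,
                      condition_prevalences = rep(0.5, 4),
                      signature_sizes = c(60, 60, 60, 60), core_size = 50,
                      effect_size = 1.0, noise_sd = 0.5, seed = 7)
  sim <- simulate_cohort(spec)
  core <- truth_core(sim$truth)
  dirs <- sim$truth$direction[match(core, sim$truth$gene)]
  flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
  # directed group-mean difference, independent of the generator internals
  d_per_cond <- vapply(flags, function(f) {
    grp <- condition_groups(sim$study, f)
    d <- rowMeans(sim$study$values[core, grp$case]) -
         rowMeans(sim$study$values[core, grp$control])
    mean(d * dirs)
  }, numeric(1))
  expect_equal(unname(mean(d_per_cond)), spec$effect_size, tolerance = 0.1)
})

test_that("replanting a truth table preserves planted sets in a new cohort", {
  spec <- cohort_spec(n_genes = 200, n_samples = 40,
                      signature_sizes = c(20, 20, 20, 20), core_size = 10,
                      seed = 1)
  disc <- simulate_cohort(spec)
  spec2 <- spec; spec2$seed <- 99L; spec2$n_samples <- 30L
  repl <- simulate_cohort(spec2, truth = disc$truth)
  expect_identical(repl$truth[c("gene", "direction")],
                   disc$truth[c("gene", "direction")])
  expect_false(identical(repl$study$values[1, 1], disc$study$values[1, 1]))
  expect_equal(ncol(repl$study$values), 30)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(core_size = 200, signature_sizes = rep(50, 4)),
               "core_size")
  expect_error(cohort_spec(condition_prevalences = c(0, .5, .5, .5)),
               "prevalences")
  expect_error(cohort_spec(n_genes = 50), "fit")
})

test_that("interactome simulation plants clustered modules deterministically", {
  nodes <- sprintf("G%05d", 1:60)
  mod <- nodes[1:5]
  # full boost plants a clique
  net <- simulate_interactome(60, "erdos_renyi", planted_modules = list(mod),
                              boost = 1, p_edge = 0.02, seed = 4)
  sub <- igraph::induced_subgraph(net$graph, mod)
  expect_equal(igraph::ecount(sub), 10)
  # boosted edges exceed the 0.4 confidence threshold
  expect_true(all(igraph::E(sub)$score > 0.4))

  # seeded determinism of the degree sequence
  g1 <- simulate_interactome(80, "powerlaw_cluster", seed = 11)
  g2 <- simulate_interactome(80, "powerlaw_cluster", seed = 11)
  expect_identical(igraph::degree(g1$graph), igraph::degree(g2$graph))
  expect_error(simulate_interactome(5), ">= 10")
  expect_error(simulate_interactome(20, planted_modules = list("ZZZ")),
               "absent")
})

test_that("zero boost leaves planted density at background level", {
  nodes <- sprintf("G%05d", 1:200)
  mod <- nodes[1:30]
  dens <- function(net, set) {
    sub <- igraph::induced_subgraph(net$graph, set)
    igraph::ecount(sub) / choose(length(set), 2)
  }
  d_mod <- d_bg <- numeric(10)
  for (s in 1:10) {
    net <- simulate_interactome(200, "erdos_renyi",
                                planted_modules = list(mod),
                                boost = 0, p_edge = 0.05, seed = s)
    d_mod[s] <- dens(net, mod)
    d_bg[s] <- igraph::ecount(net$graph) / choose(200, 2)
  }
  expect_equal(mean(d_mod), mean(d_bg), tolerance = 0.25)
})

test_that("ontology simulation yields a rooted typed DAG with exact annotation counts", {
  genes <- sprintf("g%03d", 1:20)
  out <- simulate_ontology(50, max_depth = 4, part_of_fraction = 0.3,
                           genes = genes, annotations_per_gene = 3, seed = 2)
  dag <- out$dag
  expect_s3_class(dag, "OntologyDag")     # ontology_dag() enforces acyclicity
  expect_equal(dag$roots, "T0001")
  expect_true(all(dag$edges$relation %in% c("is_a", "part_of")))
  counts <- table(out$annotations$gene)
  expect_true(all(counts == 3))
  # star DAG at max_depth 1
  star <- simulate_ontology(10, max_depth = 1, part_of_fraction = 0,
                            second_parent_prob = 0, seed = 5)$dag
  expect_true(all(star$edges$parent == "T0001"))
  expect_true(all(star$edges$relation == "is_a"))
  # acyclicity holds for many seeds (constructor would error otherwise)
  for (s in 1:20)
    expect_s3_class(simulate_ontology(30, seed = s)$dag, "OntologyDag")
})

test_that("placenta simulation plants the exact concordant core fraction", {
  spec <- cohort_spec(n_genes = 500, n_samples = 60,
                      signature_sizes = rep(100, 4), core_size = 100, seed = 9)
  blood <- simulate_cohort(spec)
  pl <- simulate_placenta(blood$truth, concordance = 0.4, n_samples = 30,
                          seed = 21)
  expect_equal(sum(pl$truth$planted), 40)   # round-half-even of 0.4 * 100
  expect_true(all(pl$truth$gene[pl$truth$planted] %in% truth_core(blood$truth)))
  # concordant directions with blood
  pk <- pl$truth[pl$truth$planted, ]
  expect_identical(pk$direction,
                   blood$truth$direction[match(pk$gene, blood$truth$gene)])
  # reproducible planted set
  pl2 <- simulate_placenta(blood$truth, 0.4, n_samples = 30, seed = 21)
  expect_identical(pl$truth, pl2$truth)
  expect_identical(pl$study$values, pl2$study$values)
  # boundary concordances
  expect_equal(sum(simulate_placenta(blood$truth, 1, seed = 1)$truth$planted), 100)
  expect_equal(sum(simulate_placenta(blood$truth, 0, seed = 1)$truth$planted), 0)
  expect_error(simulate_placenta(blood$truth, 1.2), "concordance")
})

test_that("study TSV round-trip preserves values and phenotypes", {
  spec <- cohort_spec(n_genes = 30, n_samples = 8,
                      signature_sizes = rep(5, 4), core_size = 2, seed = 13)
  sim <- simulate_cohort(spec)
  tf1 <- tempfile(fileext = ".tsv"); tf2 <- tempfile(fileext = ".tsv")
  write_study_tsv(sim$study, tf1, tf2)
  back <- read_study_tsv(tf1, tf2)
  expect_equal(back$values, sim$study$values, tolerance = 1e-12)
  expect_equal(back$phenotypes$PE, sim$study$phenotypes$PE)
})
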