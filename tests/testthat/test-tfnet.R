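test_that("promoter-window annotation respects half-open boundaries", {
  tss <- tss_table("g1", "chr1", 10000, "+")
  # inside the window
  pk <- genomic_intervals("chr1", 9500, 9600, "A")
  expect_identical(bound_tfs(annotate_binding(pk, tss), "g1"), "A")
  # gap beyond 2 kb downstream: window is [8000, 12000)
  pk2 <- genomic_intervals("chr1", 12001, 12100, "A")
  expect_length(annotate_binding(pk2, tss), 0)
  # 1 bp overlap at the inclusive window start
  pk3 <- genomic_intervals("chr1", 8000, 8001, "A")
  expect_identical(bound_tfs(annotate_binding(pk3, tss), "g1"), "A")
  # just left of the window
  pk4 <- genomic_intervals("chr1", 7999, 8000, "A")
  expect_length(annotate_binding(pk4, tss), 0)
  # different chromosome never binds
  pk5 <- genomic_intervals("chr2", 9500, 9600, "A")
  expect_length(annotate_binding(pk5, tss), 0)
})

test_that("binding edges are monotone in the window size", {
  set.seed(41)
  tss <- tss_table(sprintf("g%02d", 1:10), "chr1",
                   seq(5000, by = 10000, length.out = 10),
                   rep("+", 10))
  pos <- sample(0:100000, 200, replace = TRUE)
  pk <- genomic_intervals("chr1", pos, pos + 150,
                          sample(c("A", "B", "C"), 200, replace = TRUE))
  edge_set <- function(map) {
    unlist(lapply(names(map), function(tf) paste(tf, map[[tf]])))
  }
  e1 <- edge_set(annotate_binding(pk, tss, window = 500))
  e2 <- edge_set(annotate_binding(pk, tss, window = 2000))
  e3 <- edge_set(annotate_binding(pk, tss, window = 5000))
  expect_true(all(e1 %in% e2))
  expect_true(all(e2 %in% e3))
})

make_tf_toy <- function(n = 60, noise = 0, seed = 2, w = 2) {
  set.seed(seed)
  ids <- sprintf("s%02d", 1:n)
  tf_expr <- matrix(rnorm(2 * n), 2, dimnames = list(c("TF1", "TF2"), ids))
  g <- w * tf_expr["TF1", ] + rnorm(n, sd = noise)
  expr <- expression_matrix(matrix(g, 1, dimnames = list("g1", ids)), "d")
  st <- sample_table(ids, rep("TNBC", n))
  binding <- structure(list(TF1 = "g1", TF2 = "g1"), class = "binding_map")
  list(expr = expr, tf_expr = expression_matrix(tf_expr, "d"),
       samples = st, binding = binding)
}

test_that("a noiseless TF driver is selected in every repetition", {
  toy <- make_tf_toy(noise = 0)
  prof <- stability_select("g1", toy$expr, toy$tf_expr, NULL, NULL,
                           toy$samples, "TNBC", toy$binding, n_rep = 20,
                           seed = 5)
  expect_equal(unname(prof$frequency["TF1"]), 1.0)
  expect_lte(unname(prof$frequency["TF2"]), 0.3)
})

test_that("stability frequencies are deterministic and order-invariant", {
  toy <- make_tf_toy(noise = 0.5)
  p1 <- stability_select("g1", toy$expr, toy$tf_expr, NULL, NULL,
                         toy$samples, "TNBC", toy$binding, n_rep = 15,
                         seed = 9)
  p2 <- stability_select("g1", toy$expr, toy$tf_expr, NULL, NULL,
                         toy$samples, "TNBC", toy$binding, n_rep = 15,
                         seed = 9)
  expect_identical(p1, p2)

  flipped <- toy$tf_expr[c("TF2", "TF1"), ]
  p3 <- stability_select("g1", toy$expr,
                         expression_matrix(flipped, "d"), NULL, NULL,
                         toy$samples, "TNBC",
                         structure(list(TF2 = "g1", TF1 = "g1"),
                                   class = "binding_map"),
                         n_rep = 15, seed = 9)
  expect_equal(sort(names(p3$frequency)), sort(names(p1$frequency)))
})

test_that("genes without ChIP evidence yield an empty profile", {
  toy <- make_tf_toy()
  expect_message(
    prof <- stability_select("g1", toy$expr, toy$tf_expr, NULL, NULL,
                             toy$samples, "TNBC",
                             structure(list(), class = "binding_map"),
                             n_rep = 5, seed = 1),
    "no ChIP-bound TF")
  expect_length(prof$frequency, 0)
  expect_null(choose_threshold(prof, toy$expr, toy$tf_expr, NULL, NULL,
                               toy$samples))
})

test_that("threshold choice prefers the sparser tie on a clean signal", {
  toy <- make_tf_toy(noise = 0)
  prof <- stability_select("g1", toy$expr, toy$tf_expr, NULL, NULL,
                           toy$samples, "TNBC", toy$binding, n_rep = 20,
                           seed = 5)
  ch <- choose_threshold(prof, toy$expr, toy$tf_expr, NULL, NULL,
                         toy$samples, seed = 5)
  expect_identical(ch$retained, "TF1")
  # every threshold above the decoy frequency retains exactly TF1, so the
  # R^2 tie resolves to the largest threshold
  expect_equal(ch$threshold, 0.9)
  ch2 <- choose_threshold(prof, toy$expr, toy$tf_expr, NULL, NULL,
                          toy$samples, seed = 5)
  expect_identical(ch, ch2)
})

test_that("differential networks are pure edge-set subtraction", {
  t_net <- bipartite_network(c("A", "A"), c("g1", "g2"), c(1, 1), "TNBC")
  n_net <- bipartite_network("A", "g2", 1, "non-TNBC")
  dn <- differential_network(t_net, n_net)
  expect_identical(dn$edges$gene, "g1")
  expect_identical(unname(dn$tf_counts["A"]), 1L)

  same <- differential_network(t_net, t_net)
  expect_identical(nrow(same$edges), 0L)
})

test_that("master regulators rank by target count with a name tiebreak", {
  net <- read_edge_list(fixture_path("tnbc_tf_targets.tsv"))
  dn <- differential_network(net, bipartite_network(group = "non-TNBC"))
  mr <- master_regulators(dn, min_targets = 4)
  expect_identical(nrow(mr), 10L)
  expect_identical(mr$tf[1], "AR")
  expect_identical(mr$n_targets[1], 7L)
  expect_true(all(diff(mr$n_targets) <= 0))

  mr6 <- master_regulators(dn, min_targets = 6)
  expect_identical(mr6$tf, c("AR", "TCF7L2"))

  empty <- differential_network(bipartite_network(group = "TNBC"),
                                bipartite_network(group = "non-TNBC"))
  expect_identical(nrow(master_regulators(empty)), 0L)
})

test_that("planted TNBC-only edges are recovered by group-network subtraction", {
  edges <- data.frame(tf = sprintf("TF%02d", 1:3),
                      gene = sprintf("G%03d", 1:6),
                      group = "TNBC", w = 1)
  cfg <- simulation_config(n_genes = 8, n_tfs = 10, n_per_group = 150,
                           n_cohorts = 1, de_fraction = 0, noise_sd = 0.5,
                           tf_edges = edges, n_null_sets = 0, seed = 17)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  bm <- annotate_binding(sim$peaks, sim$tss)
  genes <- rownames(co$expression)
  net_t <- build_group_network(genes, co$expression, co$tf_expression,
                               co$cna, co$dm, co$samples, bm, "TNBC",
                               seed = 1)
  net_n <- build_group_network(genes, co$expression, co$tf_expression,
                               co$cna, co$dm, co$samples, bm, "non-TNBC",
                               seed = 1)
  dn <- differential_network(net_t, net_n)
  truth_keys <- paste(edges$tf, edges$gene)
  got_keys <- paste(dn$edges$tf, dn$edges$gene)
  expect_gte(mean(truth_keys %in% got_keys), 0.8)   # recall
  expect_gte(mean(got_keys %in% truth_keys), 0.8)   # precision
})

test_that("shared TF wiring leaves the differential network near-empty", {
  edges <- data.frame(tf = c("TF01", "TF02"), gene = c("G001", "G002"),
                      group = "both", w = 1.5)
  spurious <- 0
  for (seed in 1:2) {
    cfg <- simulation_config(n_genes = 6, n_tfs = 6, n_per_group = 120,
                             n_cohorts = 1, de_fraction = 0, noise_sd = 0.5,
                             tf_edges = edges, n_null_sets = 0, seed = seed)
    sim <- simulate_cohorts(cfg)
    co <- sim$cohorts[[1]]
    bm <- annotate_binding(sim$peaks, sim$tss)
    genes <- rownames(co$expression)
    net_t <- build_group_network(genes, co$expression, co$tf_expression,
                                 co$cna, co$dm, co$samples, bm, "TNBC",
                                 seed = 1)
    net_n <- build_group_network(genes, co$expression, co$tf_expression,
                                 co$cna, co$dm, co$samples, bm, "non-TNBC",
                                 seed = 1)
    spurious <- spurious + nrow(differential_network(net_t, net_n)$edges)
  }
  expect_lte(spurious / 2, 1)
})
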