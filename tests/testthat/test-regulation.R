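test_that("Spearman correlations match the rank formula and are monotone-invariant", {
  ids <- c("s1", "s2", "s3")
  row_mat <- function(v) matrix(v, 1, dimnames = list("g1", ids))
  st <- sample_table(ids, rep("TNBC", 3))
  expr <- expression_matrix(row_mat(c(1, 2, 3)), "d")
  layer <- expression_matrix(row_mat(c(3, 1, 2)), "d")
  # the empty non-TNBC stratum is reported undefined with a warning
  tab <- suppressWarnings(spearman_by_group(expr, layer, st,
                                            regulator = "CNA"))
  expect_equal(tab$rho[tab$group == "TNBC"], -0.5, tolerance = 1e-12)

  layer2 <- expression_matrix(row_mat(2 * c(1, 2, 3) + 1), "d")
  tab2 <- suppressWarnings(spearman_by_group(expr, layer2, st))
  expect_equal(tab2$rho[tab2$group == "TNBC"], 1)

  flat <- expression_matrix(row_mat(c(2, 2, 2)), "d")
  expect_warning(tab3 <- spearman_by_group(expr, flat, st), "undefined")
  expect_true(is.na(tab3$rho[tab3$group == "TNBC"]))
})

test_that("missing values are excluded pairwise", {
  ids <- sprintf("s%d", 1:6)
  st <- sample_table(ids, rep(c("TNBC", "non-TNBC"), each = 3))
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 4, NA, 8, 10, 12)
  expr <- expression_matrix(matrix(x, 1, dimnames = list("g1", ids)), "d")
  layer <- expression_matrix(matrix(y, 1, dimnames = list("g1", ids)), "d")
  tab <- spearman_by_group(expr, layer, st, min_pairs = 2)
  expect_equal(tab$n[tab$group == "TNBC"], 2)
  expect_equal(tab$rho[tab$group == "all"], 1)
  other <- matrix(1:3, 1, dimnames = list("g1", c("t1", "t2", "t3")))
  expect_error(spearman_by_group(expr, expression_matrix(other, "d"), st),
               "shared samples")
})

test_that("strength classes cover [-1, 1] at the published thresholds", {
  expect_identical(classify_strength(0.450)$class, "strong")
  expect_identical(classify_strength(0.449)$class, "moderate")
  expect_identical(classify_strength(0.300)$class, "moderate")
  expect_identical(classify_strength(0.299)$class, "weak")
  expect_identical(classify_strength(0.100)$class, "weak")
  expect_identical(classify_strength(0.099)$class, "low/no")
  expect_identical(classify_strength(-0.7)$class, "strong")

  dm <- classify_strength(-0.05, regulator = "DM")
  expect_identical(dm$class, "low/no")
  expect_true(dm$dm_sign_consistent)
  expect_false(classify_strength(0.3, "DM")$dm_sign_consistent)

  grid <- seq(-1, 1, by = 0.001)
  cls <- classify_strength(grid)$class
  expect_false(anyNA(cls))
  expect_identical(sort(unique(cls)),
                   sort(c("strong", "moderate", "weak", "low/no")))
})

test_that("differential correlation is the absolute group difference", {
  tab <- data.frame(
    gene = rep(c("g1", "g2", "g3"), each = 2),
    group = rep(c("TNBC", "non-TNBC"), 3),
    regulator = "CNA",
    rho = c(0.5, 0.2, 0.4, 0.4, -0.4, 0.6),
    n = 10, class = NA, stringsAsFactors = FALSE)
  dc <- delta_cor(tab)
  expect_equal(dc$delta_cor[dc$gene == "g1"], 0.3)
  expect_equal(dc$delta_cor[dc$gene == "g2"], 0)
  expect_equal(dc$delta_cor[dc$gene == "g3"], 1.0)
  expect_true(all(dc$delta_cor >= 0 & dc$delta_cor <= 2))

  tab$rho[2] <- NA
  expect_message(dc2 <- delta_cor(tab), "missing")
  expect_true(is.na(dc2$delta_cor[dc2$gene == "g1"]))
})

test_that("the rank-sum regulation test has the enumerated exact null", {
  tab <- data.frame(gene = rep(c("g1", "g2"), each = 2),
                    group = rep(c("TNBC", "non-TNBC"), 2),
                    regulator = "CNA",
                    rho = c(0.9, 0.1, 0.8, 0.2),
                    n = 10, class = NA, stringsAsFactors = FALSE)
  res <- test_differential_regulation(tab)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)  # 2 / C(4,2)

  # degenerate: identical single shared value in both groups
  tab2 <- tab; tab2$rho <- c(0.5, 0.5, 0.5, 0.5)
  expect_equal(test_differential_regulation(tab2)$p, 1)

  small <- tab[tab$gene == "g1", ]
  expect_message(out <- test_differential_regulation(small,
    groupings = list(tiny = "g1")), "skipping")
  expect_identical(nrow(out), 0L)
})

test_that("the regulation test rejects at the nominal rate under the null", {
  set.seed(77)
  rej <- 0
  n_sim <- 2000
  for (i in seq_len(n_sim)) {
    rho_t <- runif(8, -1, 1)
    rho_n <- runif(8, -1, 1)
    p <- suppressWarnings(wilcox.test(rho_t, rho_n, exact = FALSE,
                                      correct = TRUE)$p.value)
    tab <- data.frame(gene = rep(sprintf("g%d", 1:8), each = 2),
                      group = rep(c("TNBC", "non-TNBC"), 8),
                      regulator = "CNA", rho = as.vector(rbind(rho_t, rho_n)),
                      n = 10, class = NA, stringsAsFactors = FALSE)
    if (test_differential_regulation(tab)$p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_sim - 0.05), 0.025)
})

test_that("CNA- and DM-driven genes separate by correlation profile", {
  cfg <- simulation_config(n_genes = 30, n_tfs = 2, n_per_group = 150,
                           n_cohorts = 1, de_fraction = 0, noise_sd = 0.5,
                           cna_driven = 1:5, cna_alpha = 1,
                           dm_driven = 6:10, dm_beta = -4,
                           n_null_sets = 0, seed = 31)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  tab_cna <- spearman_by_group(co$expression, co$cna, co$samples, "CNA")
  tab_dm <- spearman_by_group(co$expression, co$dm, co$samples, "DM")
  all_cna <- tab_cna[tab_cna$group == "all", ]
  all_dm <- tab_dm[tab_dm$group == "all", ]
  cna_g <- sim$truth$cna_driven
  dm_g <- sim$truth$dm_driven
  m_cna <- mean(abs(all_cna$rho[all_cna$gene %in% cna_g]))
  m_cna_dm <- mean(abs(all_dm$rho[all_dm$gene %in% cna_g]))
  m_dm <- mean(abs(all_dm$rho[all_dm$gene %in% dm_g]))
  m_dm_cna <- mean(abs(all_cna$rho[all_cna$gene %in% dm_g]))
  expect_gte(m_cna - m_cna_dm, 0.2)
  expect_gte(m_dm - m_dm_cna, 0.2)
  # DM coupling is repressive: negative correlation for DM-driven genes
  expect_true(all(all_dm$rho[all_dm$gene %in% dm_g] < 0))
})

test_that("group-specific TF wiring raises deltaCor above null genes", {
  edges <- data.frame(tf = c("TF01", "TF02"), gene = c("G001", "G002"),
                      group = "TNBC", w = 1.5)
  deltas <- c(); nulls <- c()
  for (seed in 1:5) {
    cfg <- simulation_config(n_genes = 12, n_tfs = 4, n_per_group = 80,
                             n_cohorts = 1, de_fraction = 0, noise_sd = 0.5,
                             cna_driven = 1:12, cna_alpha = 0.7,
                             tf_edges = edges, n_null_sets = 0, seed = seed)
    sim <- simulate_cohorts(cfg)
    co <- sim$cohorts[[1]]
    tab <- spearman_by_group(co$expression, co$cna, co$samples, "CNA")
    dc <- delta_cor(tab)
    deltas <- c(deltas, dc$delta_cor[dc$gene %in% c("G001", "G002")])
    nulls <- c(nulls, dc$delta_cor[!dc$gene %in% c("G001", "G002")])
  }
  expect_gt(mean(deltas), mean(nulls))
})

test_that("top differential-correlation report is ordered and bounded", {
  set.seed(12)
  tab <- data.frame(gene = rep(sprintf("g%02d", 1:15), each = 2),
                    group = rep(c("TNBC", "non-TNBC"), 15),
                    regulator = "CNA", rho = runif(30, -1, 1),
                    n = 20, class = NA, stringsAsFactors = FALSE)
  top <- top_delta_cor(delta_cor(tab), n = 10)
  expect_identical(nrow(top), 10L)
  expect_true(all(diff(top$delta_cor) <= 0))
})
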