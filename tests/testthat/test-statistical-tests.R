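test_that("exact Wilcoxon p equals full rank-arrangement enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  set.seed(17)
  for (rep in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:8, 1)
    vals <- sample(1000, na + nb)   # no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    w <- wilcoxon_rank_sum(a, b)
    expect_equal(w$method, "exact")
    expect_equal(w$p_value, wilcox_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles identical samples and large/tied inputs", {
  a <- c(1, 5, 9, 12)
  expect_gt(wilcoxon_rank_sum(a, a)$p_value, 0.99)
  set.seed(23)
  a <- rnorm(40); b <- rnorm(45, 0.2)
  w <- wilcoxon_rank_sum(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(wilcoxon_rank_sum(numeric(0), a), "non-empty")
})

test_that("limiting-similarity test detects planted within-phylum competition", {
  set.seed(31)
  taxa <- paste0("T", 1:16)
  phy <- rep(c("Bacteroidetes", "Firmicutes"), each = 8)
  tax <- toy_taxonomy(taxa, phylum = phy)
  same <- outer(phy, phy, "==")
  beta <- matrix(NA_real_, 16, 16, dimnames = list(taxa, taxa))
  beta[same] <- rnorm(sum(same), -0.5, 0.1)
  beta[!same] <- rnorm(sum(!same), 0.1, 0.1)
  sig <- matrix(TRUE, 16, 16, dimnames = list(taxa, taxa))
  net <- toy_network(beta, sig)
  res <- limiting_similarity_test(net, tax)
  expect_lt(res$p_within_more_negative, 0.001)
  expect_lt(res$p_two_sided, 0.001)

  # toggling the diagonal moves exactly the significant diagonal models
  res_nd <- limiting_similarity_test(net, tax, include_diagonal = FALSE)
  expect_equal(res$n_within - res_nd$n_within, 16L)
  expect_equal(res$n_between, res_nd$n_between)

  # empty pool flag
  sig2 <- sig; sig2[same] <- FALSE
  res2 <- limiting_similarity_test(toy_network(beta, sig2), tax)
  expect_equal(res2$flag, "empty_pool")
})

test_that("limiting-similarity p-values are uniform under a shared null", {
  set.seed(55)
  taxa <- paste0("T", 1:20)
  phy <- rep(c("A", "B", "C", "D"), each = 5)
  tax <- toy_taxonomy(taxa, phylum = phy)
  ps <- replicate(100, {
    beta <- matrix(rnorm(400), 20, 20, dimnames = list(taxa, taxa))
    sig <- matrix(runif(400) < 0.5, 20, 20, dimnames = list(taxa, taxa))
    limiting_similarity_test(toy_network(beta, sig), tax)$p_two_sided
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("reverse-ecology tables validate ranges and restrict to phylum sets", {
  sp <- c("s1", "s2", "s3", "s4")
  phy <- c("Bacteroidetes", "Bacteroidetes", "Firmicutes", "Cyanobacteria")
  pairs <- expand.grid(a = sp, b = sp, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  set.seed(41)
  pairs$competition <- runif(nrow(pairs))
  pairs$complementarity <- runif(nrow(pairs))
  re <- re_table(sp, phy,
                 competition = data.frame(a = pairs$a, b = pairs$b,
                                          value = pairs$competition),
                 complementarity = data.frame(a = pairs$a, b = pairs$b,
                                              value = pairs$complementarity))
  expect_equal(unname(diag(re$competition)), rep(1, 4))

  # species outside the modelled phyla are excluded before testing
  res <- re_limiting_similarity(re, phyla = c("Bacteroidetes", "Firmicutes"))
  expect_equal(res$n_species, 3L)
  # D matrix over 3 species: 6 ordered off-diagonal cells
  expect_equal(res$n_within + res$n_between, 6L)

  expect_equal(re_limiting_similarity(re, phyla = "Firmicutes")$flag,
               "single_phylum")
  expect_error(re_table(sp, phy, matrix(2, 4, 4), matrix(0.5, 4, 4)),
               "\\[0, 1\\]")
})

test_that("planted within-phylum metabolic overlap yields a lower within D", {
  set.seed(43)
  n <- 12
  sp <- paste0("s", 1:n)
  phy <- rep(c("Bacteroidetes", "Firmicutes"), each = n / 2)
  same <- outer(phy, phy, "==")
  comp <- matrix(runif(n * n, 0.1, 0.3), n, n)
  comp[same] <- runif(sum(same), 0.6, 0.9)   # stronger overlap within
  compl <- matrix(runif(n * n, 0.3, 0.5), n, n)
  comp <- (comp + t(comp)) / 2
  re <- re_table(sp, phy, comp, compl)
  res <- re_limiting_similarity(re)
  expect_lt(res$p_within_more_negative, 0.001)
})

test_that("reverse-ecology connectedness sums match brute force", {
  sp <- c("x", "y")
  re <- re_table(sp, c("P1", "P2"),
                 competition = data.frame(a = "x", b = "y", value = 0.4),
                 complementarity = data.frame(a = "x", b = "y", value = 0.2))
  rc <- re_connectedness(re)
  expect_equal(rc$competition_sum, c(0.4, 0.4))
  expect_equal(rc$complementarity_sum, c(0.2, 0.2))

  set.seed(47)
  n <- 8
  sp <- paste0("s", 1:n)
  phy <- sample(c("A", "B", "C"), n, replace = TRUE)
  comp <- matrix(runif(n * n), n, n); comp <- (comp + t(comp)) / 2
  compl <- matrix(runif(n * n), n, n); compl <- (compl + t(compl)) / 2
  re2 <- re_table(sp, phy, comp, compl)
  rc2 <- re_connectedness(re2)
  for (p in unique(phy)) {
    brute <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (phy[i] == p || phy[j] == p) brute <- brute + comp[i, j]
    expect_equal(rc2$competition_sum[rc2$phylum == p], brute,
                 tolerance = 1e-10)
  }
})

test_that("subsampling at or above the full size reproduces the full model exactly", {
  ds <- make_benchmark("sparse", seed = 5, n_taxa = 8, n_days = 150)
  pre <- run_preprocess(ds$table, ds$taxonomy)
  rb <- subsample_robustness(pre, max_points_list = c(1000, 500),
                             reps = 3, seed = 2)
  expect_equal(rb$mean_r, c(1, 1))
  expect_equal(rb$mean_power, rep(attr(rb, "full_power"), 2))
})

test_that("subsampling replicates are reproducible under a fixed seed", {
  ds <- make_benchmark("sparse", seed = 5, n_taxa = 6, n_days = 150)
  pre <- run_preprocess(ds$table, ds$taxonomy)
  r1 <- subsample_robustness(pre, c(80, 50), reps = 4, seed = 9)
  r2 <- subsample_robustness(pre, c(80, 50), reps = 4, seed = 9)
  expect_identical(r1, r2)
  expect_error(subsample_robustness(pre, 1), "at least 2")
})

test_that("co-occurrence matrix equals a rank-then-Pearson oracle", {
  ds <- make_benchmark("null", seed = 13, n_taxa = 6, n_days = 120)
  pre <- run_preprocess(ds$table, ds$taxonomy)
  rho <- cooccurrence_matrix(pre)
  taxa <- rownames(rho)
  x <- pre$rel_abund[, taxa]
  oracle <- stats::cor(apply(x, 2, rank))
  expect_equal(unname(rho), unname(oracle), tolerance = 1e-10)
  expect_equal(diag(rho), rep(1, length(taxa)), ignore_attr = TRUE)

  # perfect monotone relations
  y <- cbind(a = 1:30, b = (1:30)^2, c = 30:1)
  pt <- processed_table_from_log(log(y))
  pt$rel_abund <- y; pt$counts <- y
  pt$t_index <- 1:30
  rr <- cooccurrence_matrix(pt, inference_config(min_prev = 0))
  expect_equal(rr["a", "b"], 1)
  expect_equal(rr["a", "c"], -1)
})

test_that("co-occurrence versus beta finds planted monotone and nonlinear links", {
  set.seed(61)
  n <- 12
  taxa <- paste0("T", 1:n)
  rho <- matrix(0, n, n, dimnames = list(taxa, taxa))
  vals <- runif(n * (n - 1) / 2, -1, 1)
  rho[upper.tri(rho)] <- vals
  rho <- rho + t(rho); diag(rho) <- 1
  beta <- -rho   # planted exact inverse relation
  sig <- matrix(TRUE, n, n, dimnames = list(taxa, taxa))
  net <- toy_network(beta, sig)
  res <- cooccurrence_vs_beta(rho, net)
  expect_equal(res$spearman_r, -1, tolerance = 1e-10)
  expect_lt(res$smooth_p, 1e-6)

  # independent rho and beta: no relation
  beta2 <- matrix(rnorm(n * n), n, n, dimnames = list(taxa, taxa))
  res2 <- cooccurrence_vs_beta(rho, toy_network(beta2, sig))
  expect_gt(res2$spearman_p, 0.001)

  small <- toy_network(matrix(rnorm(4), 2, 2,
                              dimnames = list(c("T1", "T2"), c("T1", "T2"))),
                       matrix(TRUE, 2, 2))
  expect_equal(cooccurrence_vs_beta(rho[1:2, 1:2], small)$flag,
               "insufficient_pairs")
})
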