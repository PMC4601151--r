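test_that("the sign/significance truth table is total and matches the ecological scheme", {
  # exhaustive enumeration over the 3x3 sign combinations
  expected <- list(
    "1,1" = "cooperation", "-1,-1" = "competition",
    "1,-1" = "exploitation", "-1,1" = "exploitation",
    "1,0" = "commensalism", "0,1" = "commensalism",
    "-1,0" = "amensalism", "0,-1" = "amensalism",
    "0,0" = "none")
  for (s1 in c(-1, 0, 1)) for (s2 in c(-1, 0, 1))
    expect_equal(pair_category(s1, s2),
                 expected[[paste(s1, s2, sep = ",")]],
                 info = paste("signs", s1, s2))
})

test_that("pair classification uses significance-masked signs, diagonal excluded", {
  beta <- matrix(c(-9, 0.5, -0.2,
                   0.4, -9, 0.3,
                   -0.7, 0.1, -9), 3, 3, byrow = TRUE)
  sig <- matrix(c(TRUE, TRUE, FALSE,
                  TRUE, TRUE, FALSE,
                  TRUE, FALSE, TRUE), 3, 3, byrow = TRUE)
  net <- toy_network(beta, sig)
  cats <- classify_pairs(net)
  expect_equal(nrow(cats), 3L)  # 3 unordered pairs, no diagonal
  get <- function(a, b) cats$category[cats$taxon_a == a & cats$taxon_b == b]
  expect_equal(get("T1", "T2"), "cooperation")    # +0.5 sig / +0.4 sig
  expect_equal(get("T1", "T3"), "amensalism")     # ns / -0.7 sig
  expect_equal(get("T2", "T3"), "none")           # ns / ns
})

test_that("category prevalences are fractions of interacting pairs", {
  cats <- data.frame(taxon_a = letters[1:5], taxon_b = letters[6:10],
                     category = c("competition", "competition",
                                  "amensalism", "amensalism", "none"))
  cp <- category_prevalence(cats)
  expect_equal(cp$n_interacting, 4L)
  expect_equal(cp$fractions[["competition"]], 0.5)
  expect_equal(cp$fractions[["amensalism"]], 0.5)
  expect_equal(cp$fractions[["exploitation"]], 0)  # reported, not dropped
  expect_equal(sum(cp$fractions), 1)

  none <- data.frame(taxon_a = "a", taxon_b = "b", category = "none")
  expect_true(category_prevalence(none)$empty)
})

test_that("connectedness counts roles correctly and conserves directed edges", {
  beta <- matrix(0, 3, 3); sig <- matrix(FALSE, 3, 3)
  beta[1, 2] <- 0.5; sig[1, 2] <- TRUE    # T1 dependent positive; T2 independent
  beta[3, 1] <- -0.4; sig[3, 1] <- TRUE   # T1 independent negative; T3 dependent
  net <- toy_network(beta, sig)
  rec <- connectedness(net)
  t1 <- rec[rec$taxon == "T1", ]
  expect_equal(c(t1$PD, t1$NI, t1$PI, t1$ND), c(1, 1, 0, 0))
  expect_equal(sum(rec$PI + rec$NI), sum(rec$PD + rec$ND))

  empty <- toy_network(matrix(0, 3, 3), matrix(FALSE, 3, 3))
  expect_true(all(connectedness(empty)$total == 0))

  # conservation on random masks
  set.seed(14)
  for (rep in 1:20) {
    n <- 8
    b <- matrix(rnorm(n * n), n, n)
    s <- matrix(runif(n * n) < 0.3, n, n)
    rec <- connectedness(toy_network(b, s))
    off <- s; diag(off) <- FALSE
    expect_equal(sum(rec$PI + rec$NI), sum(off))
    expect_equal(sum(rec$PD + rec$ND), sum(off))
    expect_equal(sum(rec$total), 2 * sum(off))
  }
})

test_that("positive-fraction regression flags proportional and planted cases", {
  set.seed(3)
  # proportional null: positive count is exactly 40% of total
  tot <- sample(5:40, 12)
  rec <- data.frame(taxon = paste0("T", 1:12),
                    PI = round(0.4 * tot), PD = 0,
                    NI = tot - round(0.4 * tot), ND = 0)
  rec$total <- rec$PI + rec$PD + rec$NI + rec$ND
  r <- positive_ratio_test(rec)
  expect_equal(r$flag, "ok")
  expect_gt(r$p_value, 0.05)

  # planted: hubs disproportionately positive
  rec2 <- rec
  rec2$PI <- round(rec$total * (0.1 + 0.8 * (rank(rec$total) / 12)))
  rec2$NI <- rec2$total - rec2$PI
  r2 <- positive_ratio_test(rec2)
  expect_lt(r2$p_value, 0.01)

  # all-negative network is degenerate
  rec3 <- data.frame(taxon = paste0("T", 1:6), PI = 0, PD = 0,
                     NI = 3:8, ND = 1)
  rec3$total <- rec3$NI + rec3$ND
  expect_equal(positive_ratio_test(rec3)$flag, "degenerate")

  expect_equal(positive_ratio_test(rec[1:3, ])$flag, "insufficient_data")
})

test_that("phylum summaries aggregate counts, per-genus means and abundance normalization", {
  taxa <- c("A1", "A2", "B1")
  tax <- toy_taxonomy(taxa, phylum = c("Actinobacteria", "Actinobacteria",
                                       "Bacteroidetes"))
  beta <- matrix(0, 3, 3, dimnames = list(taxa, taxa))
  sig <- matrix(FALSE, 3, 3, dimnames = list(taxa, taxa))
  beta[1, 3] <- 0.5; sig[1, 3] <- TRUE
  beta[2, 3] <- 0.5; sig[2, 3] <- TRUE
  beta[3, 1] <- 0.5; sig[3, 1] <- TRUE
  beta[3, 2] <- 0.5; sig[3, 2] <- TRUE
  net <- toy_network(beta, sig)
  rec <- connectedness(net, tax)
  # abundances: Actinobacteria 1%, Bacteroidetes 50% (rest unmodelled)
  rel <- matrix(rep(c(0.005, 0.005, 0.5), each = 4), 4, 3,
                dimnames = list(NULL, taxa))
  pt <- list(rel_abund = rel, taxa_ids = taxa)
  ps <- phylum_summaries(rec, tax, pt)
  act <- ps[ps$phylum == "Actinobacteria", ]
  bac <- ps[ps$phylum == "Bacteroidetes", ]
  expect_equal(act$n_genera_observed, 2L)
  expect_equal(act$total, 4)            # 2 PD + 2 PI over its genera
  expect_equal(act$mean_per_genus, 2)
  expect_equal(bac$total, 4)
  # same counts, 50x lower abundance -> 50x higher normalized connectedness
  expect_equal(act$abund_norm_PD / bac$abund_norm_PD, 50)
  # partition: phylum totals recover network totals
  expect_equal(sum(ps$total), 2 * sum(sig))
})

test_that("phylum mean-positive ANOVA detects planted shifts and flags degenerate designs", {
  set.seed(6)
  taxa <- paste0("T", 1:30)
  phy <- rep(c("Bacteroidetes", "Firmicutes", "Actinobacteria"), each = 10)
  tax <- toy_taxonomy(taxa, phylum = phy)
  mk_rec <- function(pos) {
    data.frame(taxon = taxa, PI = pos, PD = 0, NI = 1, ND = 1,
               total = pos + 2)
  }
  same <- mk_rec(rpois(30, 5))
  r1 <- phylum_positive_mean_test(same, tax)
  expect_equal(r1$flag, "ok")

  shifted <- mk_rec(rpois(30, 5) + rep(c(5, 0, 0), each = 10))
  r2 <- phylum_positive_mean_test(shifted, tax)
  expect_lt(r2$p_value, 0.01)
  expect_gt(unname(r2$means["Bacteroidetes"]),
            unname(r2$means["Firmicutes"]))

  two <- mk_rec(rpois(30, 5))[c(1, 11), ]
  expect_equal(phylum_positive_mean_test(two, toy_taxonomy(
    taxa[c(1, 11)], phylum = phy[c(1, 11)]))$flag, "no_residual_df")
})

test_that("Shannon index matches closed forms and a high-precision oracle", {
  expect_equal(shannon(rep(1 / 8, 8)), log(8), tolerance = 1e-12)
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_warning(h <- shannon(c(2, 2)), "renormalizing")
  expect_equal(h, log(2), tolerance = 1e-12)
  set.seed(10)
  for (rep in 1:20) {
    p <- rdirichlet1(runif(6, 0.5, 3))
    expect_equal(shannon(p), -sum(p[p > 0] * log(p[p > 0])),
                 tolerance = 1e-10)
  }
})

test_that("diversity-abundance models detect planted log-linear relationships", {
  taxa <- c("Bifidobacterium", "F1", "F2", "F3")
  tax <- toy_taxonomy(taxa, phylum = c("Actinobacteria", rep("Firmicutes", 3)))
  # construct individuals whose mean Shannon rises exactly linearly in
  # log Actinobacteria abundance
  mk_ind <- function(a) {
    rest <- (1 - a) * c(0.5, 0.3, 0.2)
    rel <- matrix(rep(c(a, rest), each = 40), 40, 4,
                  dimnames = list(NULL, taxa))
    list(rel_abund = rel, taxa_ids = taxa)
  }
  abunds <- c(0.005, 0.02, 0.08, 0.2)
  tables <- lapply(abunds, mk_ind)
  res <- diversity_abundance_model(tables, tax, "Actinobacteria", "between")
  expect_equal(res$flag, "ok")
  expect_gt(res$r_squared, 0.9)   # H is near-linear in log a over this range
  expect_gt(res$slope, 0)

  expect_equal(
    diversity_abundance_model(tables[1:2], tax, "Actinobacteria",
                              "between")$flag,
    "insufficient_data")
  expect_equal(
    diversity_abundance_model(tables, tax, "Cyanobacteria",
                              "between")$flag,
    "phylum_absent")

  # within mode: shuffled abundances give a null slope
  set.seed(33)
  rel <- cbind(runif(60, 0.01, 0.3), matrix(runif(180), 60, 3))
  rel <- rel / rowSums(rel)
  colnames(rel) <- taxa
  one <- list(rel_abund = rel, taxa_ids = taxa)
  resw <- diversity_abundance_model(list(one), tax, "Actinobacteria",
                                    "within")[[1]]
  expect_equal(resw$flag, "ok")
  expect_equal(resw$n, 60)
})
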