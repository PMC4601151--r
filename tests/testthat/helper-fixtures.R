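# shared fixture builders for the test suite

# small count table with explicit days
toy_table <- function(counts, days = seq_len(nrow(counts)),
                      taxa = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(taxa)) colnames(counts) <- taxa
  if (!is.null(samples)) rownames(counts) <- samples
  count_table(counts, sample_day = days)
}

# taxonomy where every taxon is its own genus, phyla assignable
toy_taxonomy <- function(taxa, phylum = rep("Firmicutes", length(taxa)),
                         genus = taxa) {
  taxonomy_map(taxa, sprintf("k__Bacteria; p__%s; c__; o__; f__; g__%s",
                             phylum, genus))
}

# hand-built interaction network from beta and significance matrices
toy_network <- function(beta, significant, alpha_level = 0.01,
                        n_points = NULL) {
  beta <- as.matrix(beta)
  n <- nrow(beta)
  taxa <- rownames(beta)
  if (is.null(taxa)) {
    taxa <- paste0("T", seq_len(n))
    dimnames(beta) <- list(taxa, taxa)
  }
  significant <- matrix(as.logical(significant), n, n,
                        dimnames = dimnames(beta))
  if (is.null(n_points))
    n_points <- matrix(100, n, n, dimnames = dimnames(beta))
  net <- structure(
    list(taxa = taxa, beta = beta, alpha = beta * 0,
         p = ifelse(significant, 0.001, 0.5),
         n_points = n_points, significant = significant,
         alpha_level = alpha_level),
    class = "interaction_network")
  net$summary <- network_summary(net)
  net
}

# Dirichlet draw and two-component Dirichlet-multinomial mixture counts
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha)
  g / sum(g)
}

dm_counts <- function(n, base, concentration = 120, library = 25000) {
  t(replicate(n, as.numeric(
    stats::rmultinom(1, library, rdirichlet1(base * concentration)))))
}

# enterotype mixture fixture: Bacteroides- vs Prevotella-dominant states
dm_mixture <- function(n1 = 60, n2 = 40, n_other = 10, seed = 7) {
  set.seed(seed)
  base1 <- c(0.45, 0.02, rep(0.53 / n_other, n_other))
  base2 <- c(0.05, 0.40, rep(0.55 / n_other, n_other))
  cnt <- rbind(dm_counts(n1, base1), dm_counts(n2, base2))
  colnames(cnt) <- c("Bacteroides", "Prevotella", paste0("G", seq_len(n_other)))
  list(table = count_table(cnt, sample_day = seq_len(n1 + n2)),
       truth = rep(1:2, c(n1, n2)))
}

# processed table of independent white-noise log-abundance series: a data
# generating process under which every off-diagonal null hypothesis is true
white_noise_pt <- function(n_days = 300, n_taxa = 20, seed = 1) {
  set.seed(seed)
  y <- matrix(stats::rnorm(n_days * n_taxa), n_days, n_taxa)
  processed_table_from_log(y)
}

# brute-force Wilcoxon oracle: enumerate all assignments of the pooled
# sample to the two groups and count rank sums as extreme as observed
wilcox_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(ix)
    sum(ranks[ix]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# independent OLS oracle: normal equations + t distribution
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- crossprod(X)
  coefs <- solve(XtX, crossprod(X, y))
  res <- y - X %*% coefs
  df <- length(y) - 2L
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[2L, 2L])
  tstat <- coefs[2L] / se
  list(alpha = coefs[1L], beta = coefs[2L],
       p = 2 * stats::pt(-abs(tstat), df))
}

# adjusted Rand index (available via mclust; guarded fallback not needed --
# mclust is a test dependency)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
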