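#' Configuration for the synthetic community simulator
#'
#' The simulator mirrors the estimation model used generatively: latent
#' unnormalized log abundances follow y(t+1) = y(t) + alpha + B y(t) +
#' noise, observed through softmax (compositional) fractions and
#' multinomial sequencing counts. Defaults emulate the kind of dense daily
#' stool series the pipeline targets: a few hundred days, libraries around
#' 25,000 reads, half a dozen phyla with one numerically dominant, and
#' strongly negative self-interactions.
#'
#' @param n_taxa number of taxa.
#' @param n_days number of study days.
#' @param alpha_true per-taxon drift vector.
#' @param B_true interaction matrix on log abundances (diagonal negative);
#'   stationarity requires the spectral radius of I + B below 1.
#' @param phylum phylum label per taxon.
#' @param noise_sd process noise standard deviation (log-abundance units).
#' @param library_meanlog,library_sdlog log-normal library-size
#'   parameters (default mean about 25,000 reads).
#' @param library_floor optional lower truncation of library sizes; NULL
#'   leaves the lower tail intact so the library filter can be exercised.
#' @param missing_prob probability a day is unsampled.
#' @param duplicate_prob probability a sampled day gets a second sample.
#' @param burn_in steps discarded before day 1.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa, n_days,
                              alpha_true, B_true,
                              phylum = NULL,
                              noise_sd = 0.1,
                              library_meanlog = log(25000),
                              library_sdlog = 0.05,
                              library_floor = NULL,
                              missing_prob = 0,
                              duplicate_prob = 0,
                              burn_in = 100L) {
  B_true <- as.matrix(B_true)
  stopifnot(n_days >= 2, noise_sd > 0,
            nrow(B_true) == n_taxa, ncol(B_true) == n_taxa,
            length(alpha_true) == n_taxa)
  rad <- max(Mod(eigen(diag(n_taxa) + B_true,
                       only.values = TRUE)$values))
  if (rad >= 1)
    stop(sprintf(
      "unstable dynamics: spectral radius of I + B is %.3f (needs < 1)",
      rad))
  if (is.null(phylum)) phylum <- rep("Unassigned", n_taxa)
  structure(list(n_taxa = n_taxa, n_days = as.integer(n_days),
                 alpha_true = alpha_true, B_true = B_true,
                 phylum = phylum, noise_sd = noise_sd,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog,
                 library_floor = library_floor,
                 missing_prob = missing_prob,
                 duplicate_prob = duplicate_prob,
                 burn_in = as.integer(burn_in)),
            class = "simulation_config")
}

#' Simulate the latent log-abundance dynamics
#'
#' Iterates y(t+1) = y(t) + alpha + B y(t) + eps, eps ~ N(0, noise_sd^2),
#' initialized at the deterministic fixed point (B y* = -alpha) perturbed
#' by one noise draw, with `burn_in` steps discarded.
#'
#' @param config a [simulation_config()].
#' @return n_days x n_taxa matrix of latent log abundances.
#' @export
simulate_dynamics <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_taxa
  A <- diag(n) + config$B_true
  ystar <- solve(config$B_true, -config$alpha_true)
  y <- ystar + stats::rnorm(n, 0, config$noise_sd)
  total <- config$burn_in + config$n_days
  out <- matrix(NA_real_, config$n_days, n)
  for (t in seq_len(total)) {
    y <- drop(A %*% y) + config$alpha_true +
      stats::rnorm(n, 0, config$noise_sd)
    if (t > config$burn_in) out[t - config$burn_in, ] <- y
  }
  colnames(out) <- paste0("Genus_", formatC(seq_len(n), width = 2,
                                            flag = "0"))
  out
}

#' Closed-form stationary covariance of the latent dynamics
#'
#' Solves S = A S A' + noise_sd^2 I (A = I + B) via the Kronecker-product
#' linear system; used as an independent oracle for the simulator.
#'
#' @param config a [simulation_config()].
#' @return n_taxa x n_taxa stationary covariance matrix.
#' @export
stationary_covariance <- function(config) {
  n <- config$n_taxa
  A <- diag(n) + config$B_true
  q <- config$noise_sd^2 * diag(n)
  vecS <- solve(diag(n * n) - kronecker(A, A), as.vector(q))
  matrix(vecS, n, n)
}

#' Observe latent dynamics as sequencing counts
#'
#' Per day: softmax of the latent vector gives community fractions; a
#' library size is drawn log-normally; counts are multinomial. Days can be
#' dropped (missing) or duplicated (a second, independent library the same
#' day) to emulate real sampling schedules.
#'
#' @param latent matrix from [simulate_dynamics()].
#' @param config the matching [simulation_config()].
#' @return A [count_table()].
#' @export
sample_counts <- function(latent, config) {
  stopifnot(is.matrix(latent), all(is.finite(latent)))
  n_days <- nrow(latent)
  draw_lib <- function() {
    l <- stats::rlnorm(1, config$library_meanlog, config$library_sdlog)
    if (!is.null(config$library_floor))
      l <- max(l, config$library_floor)
    round(l)
  }
  rows <- list(); days <- integer(); ids <- character()
  k <- 0L
  for (d in seq_len(n_days)) {
    if (config$missing_prob > 0 &&
        stats::runif(1) < config$missing_prob) next
    reps <- 1L
    if (config$duplicate_prob > 0 &&
        stats::runif(1) < config$duplicate_prob) reps <- 2L
    p <- exp(latent[d, ] - max(latent[d, ]))
    p <- p / sum(p)
    for (r in seq_len(reps)) {
      k <- k + 1L
      rows[[k]] <- as.numeric(stats::rmultinom(1, draw_lib(), p))
      days[k] <- d
      ids[k] <- sprintf("D%04d%s", d, if (r > 1L) letters[r - 1L] else "")
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- ids
  colnames(counts) <- colnames(latent)
  count_table(counts, sample_day = days)
}

.default_phyla <- c("Bacteroidetes", "Firmicutes", "Actinobacteria",
                    "Proteobacteria", "Tenericutes", "Verrucomicrobia")

# heavy-tailed (power-law) target fractions; with phyla cycled over ranks the
# first phylum (holding rank 1) ends up near half the community
.target_logabund <- function(n_taxa) {
  frac <- seq_len(n_taxa)^(-1.5)
  frac <- frac / sum(frac)
  log(frac) + 10        # arbitrary shared offset; removed by compositionality
}

.assign_phyla <- function(n_taxa) {
  rep(.default_phyla, length.out = n_taxa)
}

#' Greengenes-style taxonomy for a simulated community
#' @param config a [simulation_config()].
#' @return a `taxonomy_map` for taxa Genus_01..Genus_n.
#' @export
simulated_taxonomy <- function(config) {
  n <- config$n_taxa
  ids <- paste0("Genus_", formatC(seq_len(n), width = 2, flag = "0"))
  lin <- sprintf("k__Bacteria; p__%s; c__; o__; f__; g__%s",
                 config$phylum, ids)
  taxonomy_map(ids, lin)
}

#' Benchmark datasets with known interaction structure
#'
#' Four regimes: `null` has a purely diagonal interaction matrix (no
#' off-diagonal effects, for type-I calibration); `sparse` plants 5 percent
#' of off-diagonal links at |B| = 0.3; `dense` plants 20 percent at
#' |B| = 0.15; `enterotype-switch` alternates two drift regimes in time
#' blocks — a Bacteroides-like dominant state and a Prevotella-like state —
#' with a planted reciprocal positive interaction between the two genera,
#' and records the true regime label per day. Self-interactions are -0.5
#' throughout (strong density-dependent self-limitation).
#'
#' @param regime one of "null", "sparse", "dense", "enterotype-switch".
#' @param seed RNG seed (all randomness flows from it).
#' @param n_taxa number of taxa (defaults: 20 for null/dense, 10 for
#'   sparse, 12 for enterotype-switch).
#' @param n_days number of days (default 300).
#' @param noise_sd process noise (default 0.1).
#' @return list of class `synthetic_dataset`: `table` ([count_table()]),
#'   `taxonomy`, `truth` (alpha_true, B_true, regime, and for the
#'   switching regime `regime_labels` per day), `config`.
#' @export
make_benchmark <- function(regime = c("null", "sparse", "dense",
                                      "enterotype-switch"),
                           seed = 1L, n_taxa = NULL, n_days = 300L,
                           noise_sd = 0.1) {
  regime <- match.arg(regime)
  set.seed(seed)
  if (is.null(n_taxa))
    n_taxa <- switch(regime, null = 20L, sparse = 10L, dense = 20L,
                     `enterotype-switch` = 12L)
  self <- -0.5
  target <- .target_logabund(n_taxa)
  plant <- function(density, strength) {
    B <- diag(rep(self, n_taxa))
    off <- which(diag(TRUE, n_taxa) == FALSE)
    n_links <- round(density * length(off))
    repeat {
      links <- sample(off, n_links)
      B[off] <- 0
      diag(B) <- self
      B[links] <- sample(c(-strength, strength), n_links, replace = TRUE)
      if (max(Mod(eigen(diag(n_taxa) + B, only.values = TRUE)$values)) < 1)
        break
    }
    B
  }
  if (regime != "enterotype-switch") {
    B <- switch(regime,
                null = diag(rep(self, n_taxa)),
                sparse = plant(0.05, 0.3),
                dense = plant(0.20, 0.15))
    alpha <- drop(-B %*% target)
    cfg <- simulation_config(n_taxa, n_days, alpha_true = alpha,
                             B_true = B, phylum = .assign_phyla(n_taxa),
                             noise_sd = noise_sd)
    latent <- simulate_dynamics(cfg)
    tb <- sample_counts(latent, cfg)
    truth <- list(alpha_true = alpha, B_true = B, regime = regime)
  } else {
    # taxa 1 and 2 act as Bacteroides- and Prevotella-like drivers
    B <- diag(rep(self, n_taxa))
    B[2L, 1L] <- 0.3    # strong positive influence of taxon 1 on taxon 2
    B[1L, 2L] <- 0.15   # weaker positive reciprocal
    t1 <- target; t1[1L] <- log(0.45) + 10; t1[2L] <- log(0.03) + 10
    t2 <- target; t2[1L] <- log(0.05) + 10; t2[2L] <- log(0.40) + 10
    a1 <- drop(-B %*% t1); a2 <- drop(-B %*% t2)
    half <- n_days %/% 2L
    lab <- rep(c(1L, 2L), c(half, n_days - half))
    cfg <- simulation_config(n_taxa, n_days, alpha_true = a1, B_true = B,
                             phylum = .assign_phyla(n_taxa),
                             noise_sd = noise_sd, burn_in = 100L)
    n <- n_taxa
    A <- diag(n) + B
    y <- solve(B, -a1) + stats::rnorm(n, 0, noise_sd)
    for (t in seq_len(cfg$burn_in))
      y <- drop(A %*% y) + a1 + stats::rnorm(n, 0, noise_sd)
    latent <- matrix(NA_real_, n_days, n)
    for (d in seq_len(n_days)) {
      a <- if (lab[d] == 1L) a1 else a2
      y <- drop(A %*% y) + a + stats::rnorm(n, 0, noise_sd)
      latent[d, ] <- y
    }
    colnames(latent) <- paste0("Genus_", formatC(seq_len(n), width = 2,
                                                 flag = "0"))
    tb <- sample_counts(latent, cfg)
    truth <- list(alpha_true = list(a1, a2), B_true = B,
                  regime = regime, regime_labels = lab)
  }
  structure(list(table = tb, taxonomy = simulated_taxonomy(cfg),
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}
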