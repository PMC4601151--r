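#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided rank-sum comparison of two samples. The exact null
#' distribution is used when both samples are tie-free and the smaller one
#' has at most 8 observations; otherwise the normal approximation with
#' midrank tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list with `statistic` (U for `a`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b))
    stop("both samples must be non-empty")
  no_ties <- !anyDuplicated(c(a, b))
  exact <- no_ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Limiting-similarity test on inferred interactions
#'
#' Pools the slopes of all significant models describing interactions
#' within a phylum and compares them, by Wilcoxon rank-sum, with the
#' slopes of all significant between-phylum models. Intra-genus (diagonal)
#' models are always highly negative, so the test can be run with or
#' without them. Under limiting similarity, within-phylum competition is
#' stronger, i.e. the within pool is shifted toward negative values.
#'
#' @param network an `interaction_network`.
#' @param taxonomy a `taxonomy_map` with phylum for every modelled taxon.
#' @param include_diagonal include intra-genus models in the within pool?
#' @return list with `p_two_sided`, `p_within_more_negative` (one-sided),
#'   `n_within`, `n_between`, `flag` ("ok" or "empty_pool").
#' @export
limiting_similarity_test <- function(network, taxonomy,
                                     include_diagonal = TRUE) {
  stopifnot(inherits(network, "interaction_network"))
  phy <- taxonomy_for(taxonomy, network$taxa)$phylum
  sig <- network$significant %in% TRUE
  dim(sig) <- dim(network$significant)
  same <- outer(phy, phy, "==")
  diagm <- diag(TRUE, length(network$taxa))
  if (!include_diagonal) sig <- sig & !diagm
  within <- network$beta[sig & same]
  between <- network$beta[sig & !same]
  if (!length(within) || !length(between))
    return(list(p_two_sided = NA_real_, p_within_more_negative = NA_real_,
                n_within = length(within), n_between = length(between),
                flag = "empty_pool"))
  list(p_two_sided = wilcoxon_rank_sum(within, between)$p_value,
       p_within_more_negative =
         wilcoxon_rank_sum(within, between, alternative = "less")$p_value,
       n_within = length(within), n_between = length(between),
       flag = "ok")
}

#' Build a reverse-ecology index table
#'
#' Holds genome-derived pairwise indices of metabolic competition (niche
#' overlap) and complementarity (cross-feeding potential), both normalized
#' to [0, 1]. The competition diagonal is 1 by definition (complete
#' metabolic overlap with oneself). When only one direction of a pair is
#' supplied for competition it is mirrored; complementarity is directional
#' and kept as given.
#'
#' @param species character vector of species names.
#' @param phylum phylum label per species.
#' @param competition,complementarity square matrices (species order) or
#'   long data.frames with columns `a`, `b`, `value`.
#' @return object of class `re_table`.
#' @export
re_table <- function(species, phylum, competition, complementarity) {
  stopifnot(length(species) == length(phylum))
  as_mat <- function(x, symmetrize) {
    if (is.data.frame(x)) {
      m <- matrix(NA_real_, length(species), length(species),
                  dimnames = list(species, species))
      ia <- match(x$a, species); ib <- match(x$b, species)
      if (anyNA(ia) || anyNA(ib)) stop("pair references unknown species")
      m[cbind(ia, ib)] <- x$value
      if (symmetrize) {
        fill <- is.na(m) & !is.na(t(m))
        m[fill] <- t(m)[fill]
      }
      m
    } else {
      m <- as.matrix(x)
      dimnames(m) <- list(species, species)
      m
    }
  }
  comp <- as_mat(competition, symmetrize = TRUE)
  compl <- as_mat(complementarity, symmetrize = FALSE)
  diag(comp) <- 1
  rng <- range(c(comp, compl), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("indices must lie in [0, 1]")
  structure(list(species = as.character(species),
                 phylum = as.character(phylum),
                 competition = comp, complementarity = compl),
            class = "re_table")
}

#' Read a reverse-ecology table from TSV files
#'
#' @param species_path TSV with columns `species`, `phylum`.
#' @param pairs_path long-format TSV with columns `a`, `b`, `competition`,
#'   `complementarity`.
#' @return an [re_table()].
#' @export
read_re_table <- function(species_path, pairs_path) {
  sp <- utils::read.table(species_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pr <- utils::read.table(pairs_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  re_table(sp$species, sp$phylum,
           competition = data.frame(a = pr$a, b = pr$b,
                                    value = pr$competition),
           complementarity = data.frame(a = pr$a, b = pr$b,
                                        value = pr$complementarity))
}

#' Limiting-similarity test on reverse-ecology indices
#'
#' Forms the difference D = complementarity - competition for every
#' ordered off-diagonal species pair (no antisymmetry assumed) and
#' compares within-phylum D values with between-phylum values by Wilcoxon
#' rank-sum. Species can first be restricted to a phylum set, mirroring
#' the reduction of a full genome panel to the phyla represented in the
#' time-series data.
#'
#' @param re an [re_table()].
#' @param phyla optional character vector; only species of these phyla are
#'   used.
#' @return list as in [limiting_similarity_test()], plus `n_species`.
#' @export
re_limiting_similarity <- function(re, phyla = NULL) {
  stopifnot(inherits(re, "re_table"))
  keep <- if (is.null(phyla)) rep(TRUE, length(re$species))
          else re$phylum %in% phyla
  phy <- re$phylum[keep]
  if (length(unique(phy)) < 2L)
    return(list(p_two_sided = NA_real_, p_within_more_negative = NA_real_,
                n_within = 0L, n_between = 0L,
                n_species = sum(keep), flag = "single_phylum"))
  D <- re$complementarity[keep, keep, drop = FALSE] -
    re$competition[keep, keep, drop = FALSE]
  diag(D) <- NA
  same <- outer(phy, phy, "==")
  within <- D[same & !is.na(D)]
  between <- D[!same & !is.na(D)]
  if (!length(within) || !length(between))
    return(list(p_two_sided = NA_real_, p_within_more_negative = NA_real_,
                n_within = length(within), n_between = length(between),
                n_species = sum(keep), flag = "empty_pool"))
  list(p_two_sided = wilcoxon_rank_sum(within, between)$p_value,
       p_within_more_negative =
         wilcoxon_rank_sum(within, between, alternative = "less")$p_value,
       n_within = length(within), n_between = length(between),
       n_species = sum(keep), flag = "ok")
}

#' Reverse-ecology connectedness by phylum
#'
#' Sums each index over the unordered off-diagonal pairs involving a
#' phylum's species (the RE analogue of network connectedness; higher =
#' more connected), together with per-species means.
#'
#' @param re an [re_table()].
#' @return data.frame with per-phylum `competition_sum`,
#'   `complementarity_sum`, `n_species` and per-species means.
#' @export
re_connectedness <- function(re) {
  stopifnot(inherits(re, "re_table"))
  n <- length(re$species)
  sym <- function(m) {
    s <- (ifelse(is.na(m), 0, m) + ifelse(is.na(t(m)), 0, t(m))) /
      ((!is.na(m)) + (!is.na(t(m))))
    s[is.nan(s)] <- NA
    s
  }
  comp <- sym(re$competition); compl <- sym(re$complementarity)
  out <- lapply(split(seq_len(n), re$phylum), function(ix) {
    pair_sum <- function(m) {
      tot <- 0
      for (i in ix) {
        others <- setdiff(seq_len(n), i)
        vals <- m[i, others]
        # halve pairs internal to the phylum so each unordered pair counts once
        w <- ifelse(others %in% ix, 0.5, 1)
        tot <- tot + sum(vals * w, na.rm = TRUE)
      }
      tot
    }
    data.frame(phylum = re$phylum[ix[1L]],
               n_species = length(ix),
               competition_sum = pair_sum(comp),
               complementarity_sum = pair_sum(compl),
               competition_mean = pair_sum(comp) / length(ix),
               complementarity_mean = pair_sum(compl) / length(ix))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Subsampling robustness of the inferred network
#'
#' For each level m of `max_points_list` and each of `reps` replicates,
#' every ordered pair's regression points are sampled without replacement
#' down to at most m before refitting, re-applying the usual model-size
#' floor (which drops from 50 to 25 at the m = 25 level). Two metrics are
#' averaged over replicates: the Pearson correlation between reduced and
#' full-model slopes over off-diagonal pairs fitted in both runs, and the
#' power of detection — significant off-diagonal models relative to the
#' n^2 possible interactions.
#'
#' @param table a `processed_table` (paired or not).
#' @param max_points_list integer vector of maximal point counts, e.g.
#'   `c(250, 200, 150, 125, 100, 75, 50, 25)`.
#' @param reps replicates per level (default 100).
#' @param seed RNG seed for the whole protocol.
#' @param config see [inference_config()].
#' @return data.frame with one row per level: `max_points`, `mean_r`,
#'   `mean_power`, plus the full-model power as attribute `full_power`.
#' @export
subsample_robustness <- function(table, max_points_list, reps = 100,
                                 seed = 1L, config = inference_config()) {
  stopifnot(inherits(table, "processed_table"))
  if (any(max_points_list < 2L)) stop("max_points must be at least 2")
  if (is.null(table$transitions)) table <- drop_unpaired_samples(table)
  taxa <- prevalence_filter(table, config$min_prev)
  n <- length(taxa)
  offdiag <- which(diag(TRUE, n) == FALSE)
  datasets <- vector("list", n * n)
  for (jj in seq_len(n)) for (ii in seq_len(n))
    datasets[[(jj - 1L) * n + ii]] <-
      build_pair_dataset(table, taxa[ii], taxa[jj])
  fit_all <- function(ds_list, min_points) {
    beta <- rep(NA_real_, n * n)
    sig <- rep(NA, n * n)
    for (k in seq_along(ds_list)) {
      m <- fit_pair(ds_list[[k]], min_points = min_points,
                    alpha_level = config$alpha_level)
      if (!m$excluded) {
        beta[k] <- m$beta
        sig[k] <- m$significant
      }
    }
    list(beta = beta, sig = sig)
  }
  full <- fit_all(datasets, config$min_points)
  full_power <- sum(full$sig[offdiag] %in% TRUE) / n^2
  set.seed(seed)
  rows <- lapply(max_points_list, function(m) {
    min_pts <- if (m <= 25) min(config$min_points, 25) else config$min_points
    rs <- numeric(reps); pw <- numeric(reps)
    for (r in seq_len(reps)) {
      red <- lapply(datasets, function(ds) {
        if (ds$n_points > m) {
          pick <- sample.int(ds$n_points, m)
          ds$x <- ds$x[pick]; ds$y <- ds$y[pick]; ds$n_points <- m
        }
        ds
      })
      f <- fit_all(red, min_pts)
      both <- offdiag[!is.na(full$beta[offdiag]) & !is.na(f$beta[offdiag])]
      rs[r] <- if (length(both) >= 2L &&
                   stats::sd(f$beta[both]) > 0 &&
                   stats::sd(full$beta[both]) > 0)
        stats::cor(full$beta[both], f$beta[both]) else NA_real_
      pw[r] <- sum(f$sig[offdiag] %in% TRUE) / n^2
    }
    data.frame(max_points = m,
               mean_r = mean(rs, na.rm = TRUE),
               mean_power = mean(pw))
  })
  out <- do.call(rbind, rows)
  attr(out, "full_power") <- full_power
  out
}

#' Pairwise co-occurrence (Spearman) matrix
#'
#' Contemporaneous Spearman rank correlations between the relative
#' abundance series of all modelled taxa (the same prevalence filter as
#' the regression models), zeros included. Constant series give undefined
#' correlations, returned as NA.
#'
#' @param table a `processed_table`.
#' @param config see [inference_config()] (supplies the prevalence floor).
#' @return square numeric matrix of Spearman rho over the modelled taxa.
#' @export
cooccurrence_matrix <- function(table, config = inference_config()) {
  stopifnot(inherits(table, "processed_table"))
  if (is.null(table$transitions)) table <- drop_unpaired_samples(table)
  taxa <- prevalence_filter(table, config$min_prev)
  x <- table$rel_abund[, taxa, drop = FALSE]
  suppressWarnings(rho <- stats::cor(x, method = "spearman"))
  rho
}

#' Co-occurrence versus time-series interaction coefficients
#'
#' Relates contemporaneous co-occurrence (Spearman rho) to the inferred
#' interaction slopes over ordered off-diagonal pairs — by default only
#' pairs whose model is significant. Reports the Spearman correlation
#' between rho and beta, and a smooth-term F-test from a natural cubic
#' spline regression with 3 degrees of freedom of beta on rho, which
#' accommodates non-linear relationships.
#'
#' @param cooc matrix from [cooccurrence_matrix()].
#' @param network an `interaction_network` on the same taxa.
#' @param all_models include every fitted model, not only significant ones?
#' @return list with `spearman_r`, `spearman_p`, `smooth_p`, `n_pairs`,
#'   `flag`.
#' @export
cooccurrence_vs_beta <- function(cooc, network, all_models = FALSE) {
  stopifnot(inherits(network, "interaction_network"))
  taxa <- intersect(network$taxa, rownames(cooc))
  use <- !is.na(network$beta[taxa, taxa, drop = FALSE]) &
    !is.na(cooc[taxa, taxa, drop = FALSE]) &
    !diag(TRUE, length(taxa))
  if (!all_models)
    use <- use & (network$significant[taxa, taxa, drop = FALSE] %in% TRUE)
  beta <- network$beta[taxa, taxa, drop = FALSE][use]
  rho <- cooc[taxa, taxa, drop = FALSE][use]
  if (length(beta) < 10L)
    return(list(spearman_r = NA_real_, spearman_p = NA_real_,
                smooth_p = NA_real_, n_pairs = length(beta),
                flag = "insufficient_pairs"))
  ct <- suppressWarnings(
    stats::cor.test(rho, beta, method = "spearman"))
  basis <- splines::ns(rho, df = 3)
  fit <- stats::lm(beta ~ basis)
  null <- stats::lm(beta ~ 1)
  smooth_p <- stats::anova(null, fit)[2L, "Pr(>F)"]
  list(spearman_r = unname(ct$estimate), spearman_p = ct$p.value,
       smooth_p = smooth_p, n_pairs = length(beta), flag = "ok")
}
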