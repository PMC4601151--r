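#' Identify usable day-to-day transitions
#'
#' The regression models relate the change in log abundance between
#' consecutive days to the abundance on the first of the two days, so a
#' sample is only usable as a time-t point when another sample exists on
#' the day directly after it. This function records, for each such sample,
#' the index of its day-t+1 successor. Samples without a successor are
#' dropped as time-t points, but still supply x(t+1) values for their
#' predecessors.
#'
#' @param table a `processed_table` with one sample per day.
#' @return The table with two added elements: `transitions`, a two-column
#'   integer matrix of (t, t+1) sample indices, and `t_index`, the indices
#'   of samples usable as time-t points.
#' @export
drop_unpaired_samples <- function(table) {
  stopifnot(inherits(table, "processed_table"))
  if (length(table$sample_day) < 2L)
    stop("need at least 2 samples to form transitions")
  ord <- order(table$sample_day)
  day <- table$sample_day
  succ <- match(day + 1L, day)          # index of the next-day sample
  t_index <- which(!is.na(succ))
  if (!length(t_index))
    stop("no two samples on consecutive days: no transitions available")
  table$transitions <- cbind(t = t_index, tp1 = succ[t_index])
  table$t_index <- t_index[order(day[t_index])]
  table
}

#' Days usable as time-t points
#' @param table output of [drop_unpaired_samples()].
#' @return integer vector of days kept as time-t points.
#' @export
paired_days <- function(table) {
  stopifnot(!is.null(table$t_index))
  sort(table$sample_day[table$t_index])
}

#' Prevalence filter for modelled taxa
#'
#' Taxa observed (count > 0) in fewer than `min_prev` of the time-t samples
#' are excluded from regression analysis. A taxon at exactly the threshold
#' is retained. Prevalence is computed on the post-pairing sample set.
#'
#' @param table output of [drop_unpaired_samples()].
#' @param min_prev minimum fraction of samples with a non-zero count
#'   (default 0.5).
#' @return character vector of retained taxon ids.
#' @export
prevalence_filter <- function(table, min_prev = 0.5) {
  stopifnot(inherits(table, "processed_table"))
  idx <- table$t_index %||% seq_along(table$sample_ids)
  prev <- colMeans(table$counts[idx, , drop = FALSE] > 0)
  keep <- table$taxa_ids[prev >= min_prev]
  if (!length(keep))
    stop("no taxon passes the prevalence filter")
  keep
}

#' Assemble the regression dataset for one ordered taxon pair
#'
#' A transition t -> t+1 contributes a data point to the model of dependent
#' taxon i on independent taxon j only if all three underlying log
#' abundances — x_i(t), x_i(t+1) and x_j(t) — are observed (non-zero
#' counts). The response is x_i(t+1) - x_i(t), the predictor x_j(t).
#'
#' @param table output of [drop_unpaired_samples()].
#' @param i dependent taxon id (acted upon).
#' @param j independent taxon id (acting).
#' @return A `pair_dataset`: list with `i`, `j`, `x` (predictor), `y`
#'   (response) and `n_points`.
#' @export
build_pair_dataset <- function(table, i, j) {
  stopifnot(inherits(table, "processed_table"), !is.null(table$transitions))
  L <- table$log_abund
  ti <- table$transitions[, 1L]
  tp <- table$transitions[, 2L]
  xi_t <- L[ti, i]
  xi_tp <- L[tp, i]
  xj_t <- L[ti, j]
  ok <- !is.na(xi_t) & !is.na(xi_tp) & !is.na(xj_t)
  structure(list(i = i, j = j,
                 x = unname(xj_t[ok]), y = unname((xi_tp - xi_t)[ok]),
                 n_points = sum(ok)),
            class = "pair_dataset")
}

#' Fit one pairwise first-difference regression
#'
#' Ordinary least squares of the day-to-day change in log relative
#' abundance of taxon i on the log relative abundance of taxon j, with
#' intercept. The slope is the inferred interaction coefficient; its
#' two-sided t-test p-value determines significance at `alpha_level`.
#' Models with fewer than `min_points` usable points, or with a constant
#' predictor, are excluded rather than fitted.
#'
#' @param dataset a `pair_dataset` from [build_pair_dataset()].
#' @param min_points minimum number of non-zero data points (default 50).
#' @param alpha_level significance level on the slope (default 0.01, the
#'   99 percent confidence level).
#' @return An `interaction_model` list: `i`, `j`, `alpha` (intercept),
#'   `beta` (slope), `p_value`, `n_points`, `significant`, `excluded`
#'   (FALSE), or an excluded marker (`excluded` = TRUE with a `reason`).
#' @export
fit_pair <- function(dataset, min_points = 50, alpha_level = 0.01) {
  stopifnot(inherits(dataset, "pair_dataset"))
  n <- dataset$n_points
  excl <- function(reason)
    structure(list(i = dataset$i, j = dataset$j, n_points = n,
                   excluded = TRUE, reason = reason),
              class = "interaction_model")
  if (n < max(min_points, 3L)) return(excl("too_few_points"))
  x <- dataset$x; y <- dataset$y
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) return(excl("constant_predictor"))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  resid <- y - alpha - beta * x
  df <- n - 2L
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 / sxx)
  tstat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(i = dataset$i, j = dataset$j,
                 alpha = alpha, beta = beta, p_value = p,
                 n_points = n,
                 significant = p <= alpha_level,
                 excluded = FALSE),
            class = "interaction_model")
}

#' Default inference configuration
#' @return list of the inference thresholds: 0.5 prevalence floor, 50-point
#'   model floor, significance at p <= 0.01.
#' @export
inference_config <- function(min_prev = 0.5, min_points = 50,
                             alpha_level = 0.01) {
  list(min_prev = min_prev, min_points = min_points,
       alpha_level = alpha_level)
}

#' Infer the pairwise interaction network
#'
#' Attempts all n^2 ordered pairs of the modelled taxa (n equations per
#' dependent taxon, n^2 in total), fitting each first-difference regression
#' and collecting intercepts, slopes, p-values, point counts and
#' significance flags into square matrices. Diagonal models (i = j) are the
#' intra-genus interactions, expected to be strongly negative under
#' density-dependent self-limitation.
#'
#' @param table a `processed_table` (pairing is applied if not already).
#' @param config see [inference_config()].
#' @return An `interaction_network`: taxa, matrices `alpha`, `beta`, `p`,
#'   `n_points`, `significant` (logical; NA where excluded), `alpha_level`
#'   and a `summary` list (max points, counts, neg:pos ratio, percent of
#'   possible).
#' @export
infer_network <- function(table, config = inference_config()) {
  stopifnot(inherits(table, "processed_table"))
  if (is.null(table$transitions)) table <- drop_unpaired_samples(table)
  taxa <- prevalence_filter(table, config$min_prev)
  n <- length(taxa)
  dm <- function() matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  beta <- dm(); alpha <- dm(); p <- dm(); np <- dm()
  sig <- matrix(NA, n, n, dimnames = list(taxa, taxa))
  fitted_any <- FALSE
  for (i in taxa) {
    for (j in taxa) {
      m <- fit_pair(build_pair_dataset(table, i, j),
                    min_points = config$min_points,
                    alpha_level = config$alpha_level)
      np[i, j] <- m$n_points
      if (!m$excluded) {
        fitted_any <- TRUE
        beta[i, j] <- m$beta
        alpha[i, j] <- m$alpha
        p[i, j] <- m$p_value
        sig[i, j] <- m$significant
      }
    }
  }
  if (!fitted_any)
    stop("no pair could be fitted (all excluded)")
  net <- structure(
    list(taxa = taxa, beta = beta, alpha = alpha, p = p,
         n_points = np, significant = sig,
         alpha_level = config$alpha_level),
    class = "interaction_network")
  net$summary <- network_summary(net)
  net
}

#' Summary counts of an interaction network
#'
#' The classic per-individual modelling summary: maximum number of data
#' points in any fitted model, number of significant interactions,
#' significant intra-genus (diagonal) count, ratio of negative to positive
#' significant slopes, and the percentage of the n^2 possible interactions
#' found significant.
#'
#' @param network an `interaction_network`.
#' @return list with `max_points`, `n_significant`, `n_intra_significant`,
#'   `neg_pos_ratio` (Inf when no positive), `pct_of_possible`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  sig <- network$significant %in% TRUE
  dim(sig) <- dim(network$significant)
  n <- length(network$taxa)
  nsig <- sum(sig)
  npos <- sum(sig & network$beta > 0, na.rm = TRUE)
  nneg <- sum(sig & network$beta < 0, na.rm = TRUE)
  list(max_points = max(network$n_points, na.rm = TRUE),
       n_significant = nsig,
       n_intra_significant = sum(diag(sig)),
       n_positive = npos, n_negative = nneg,
       neg_pos_ratio = if (npos > 0) nneg / npos else Inf,
       pct_of_possible = 100 * nsig / n^2)
}

#' @export
print.interaction_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "interaction_network: %d taxa, %d significant of %d possible (%.1f%%), neg:pos %s\n",
    length(x$taxa), s$n_significant, length(x$taxa)^2, s$pct_of_possible,
    if (is.finite(s$neg_pos_ratio)) sprintf("%.2f", s$neg_pos_ratio) else "Inf"))
  invisible(x)
}

#' Does model size predict significance?
#'
#' Logistic regression of the significance indicator on the number of data
#' points, across all fitted models. Under a sound modelling protocol no
#' relationship is expected between the amount of data behind a model and
#' its chance of being called significant.
#'
#' @param network an `interaction_network`.
#' @return list with `coefficient` (log-odds per point), `p_value`,
#'   `n_models`, and `degenerate` (TRUE when all or none significant, or
#'   fewer than 10 fitted models — no estimate is returned then).
#' @export
npoints_vs_significance <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  fitted <- !is.na(network$significant)
  sig <- network$significant[fitted]
  np <- network$n_points[fitted]
  if (length(sig) < 10L || all(sig) || !any(sig) ||
      stats::var(np) == 0)
    return(list(coefficient = NA_real_, p_value = NA_real_,
                n_models = length(sig), degenerate = TRUE))
  fit <- stats::glm(sig ~ np, family = stats::binomial())
  co <- summary(fit)$coefficients
  list(coefficient = co["np", "Estimate"],
       p_value = co["np", "Pr(>|z|)"],
       n_models = length(sig), degenerate = FALSE)
}
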