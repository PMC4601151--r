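#' Ecological classification of unordered taxon pairs
#'
#' Each unordered pair of distinct taxa is classified from the signs of its
#' two directed interaction coefficients, where a non-significant (or
#' excluded) direction counts as zero: cooperation (+/+), competition
#' (-/-), exploitation (+/-), commensalism (+/0), amensalism (-/0), and
#' `none` when neither direction is significant. Diagonal (intra-genus)
#' models are not pair interactions and are excluded.
#'
#' @param network an `interaction_network`.
#' @return data.frame with columns `taxon_a`, `taxon_b`, `sign_ab`,
#'   `sign_ba`, `category`.
#' @export
classify_pairs <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  taxa <- network$taxa
  n <- length(taxa)
  if (n < 2L)
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      sign_ab = integer(), sign_ba = integer(),
                      category = character()))
  effective_sign <- function(i, j) {
    if (isTRUE(network$significant[i, j])) sign(network$beta[i, j]) else 0L
  }
  rows <- list()
  k <- 0L
  for (a in 1:(n - 1L)) {
    for (b in (a + 1L):n) {
      s1 <- effective_sign(a, b)
      s2 <- effective_sign(b, a)
      k <- k + 1L
      rows[[k]] <- data.frame(taxon_a = taxa[a], taxon_b = taxa[b],
                              sign_ab = as.integer(s1),
                              sign_ba = as.integer(s2),
                              category = pair_category(s1, s2))
    }
  }
  do.call(rbind, rows)
}

#' Category of one sign pair
#'
#' @param s1,s2 signs (-1, 0, 1) of the two directed interactions of an
#'   unordered pair, with 0 meaning non-significant.
#' @return one of "cooperation", "competition", "exploitation",
#'   "commensalism", "amensalism", "none".
#' @export
pair_category <- function(s1, s2) {
  key <- paste(sort(c(s1, s2), decreasing = TRUE), collapse = "/")
  switch(key,
         "1/1" = "cooperation",
         "-1/-1" = "competition",
         "1/-1" = "exploitation",
         "1/0" = "commensalism",
         "0/-1" = "amensalism",
         "0/0" = "none",
         stop("unmappable sign combination: ", key))
}

#' Prevalence of interaction categories
#'
#' Fractions of each category relative to the total number of interacting
#' pairs (pairs in which at least one direction is significant). Categories
#' with zero observed pairs — exploitation is a common example — are
#' reported as 0, not dropped.
#'
#' @param categories output of [classify_pairs()].
#' @return list with `fractions` (named numeric over the five interaction
#'   categories), `counts`, `n_interacting`, and `empty` flag (TRUE with
#'   empty result when no pair interacts).
#' @export
category_prevalence <- function(categories) {
  lev <- c("cooperation", "competition", "exploitation",
           "commensalism", "amensalism")
  inter <- categories[categories$category != "none", , drop = FALSE]
  if (!nrow(inter))
    return(list(fractions = stats::setNames(numeric(0), character(0)),
                counts = table(factor(character(), levels = lev)),
                n_interacting = 0L, empty = TRUE))
  counts <- table(factor(inter$category, levels = lev))
  list(fractions = stats::setNames(as.numeric(counts) / nrow(inter), lev),
       counts = counts, n_interacting = nrow(inter), empty = FALSE)
}

#' Per-taxon connectedness record
#'
#' Counts each taxon's significant off-diagonal interactions split by sign
#' and role: PD/ND from its dependent role (its row: being acted upon),
#' PI/NI from its independent role (its column: acting on others). Their
#' sum is the taxon's degree of connectedness.
#'
#' @param network an `interaction_network`.
#' @param taxonomy optional `taxonomy_map`; when given, a `phylum` column
#'   is added.
#' @return data.frame with columns `taxon`, `PI`, `PD`, `NI`, `ND`,
#'   `total` (and `phylum` when taxonomy is supplied).
#' @export
connectedness <- function(network, taxonomy = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  sig <- network$significant %in% TRUE
  dim(sig) <- dim(network$significant)
  pos <- sig & !is.na(network$beta) & network$beta > 0
  neg <- sig & !is.na(network$beta) & network$beta < 0
  diag(pos) <- FALSE
  diag(neg) <- FALSE
  rec <- data.frame(taxon = network$taxa,
                    PI = colSums(pos), PD = rowSums(pos),
                    NI = colSums(neg), ND = rowSums(neg),
                    row.names = NULL)
  rec$total <- rec$PI + rec$PD + rec$NI + rec$ND
  if (!is.null(taxonomy))
    rec$phylum <- taxonomy_for(taxonomy, rec$taxon)$phylum
  rec
}

#' Is the positive share of a taxon's interactions independent of degree?
#'
#' Tests whether the ratio of positive to negative interactions a genus is
#' involved in depends on its total degree of connectedness, by regressing
#' the positive fraction (PI+PD)/total on the total. A zero slope is the
#' proportional null; a positive slope means hubs have disproportionately
#' many positive interactions.
#'
#' @param records output of [connectedness()].
#' @return list with `slope`, `p_value`, `n_taxa`, and `flag` (one of
#'   "ok", "insufficient_data", "degenerate").
#' @export
positive_ratio_test <- function(records) {
  use <- records[records$total > 0, , drop = FALSE]
  if (nrow(use) < 5L)
    return(list(slope = NA_real_, p_value = NA_real_, n_taxa = nrow(use),
                flag = "insufficient_data"))
  frac <- (use$PI + use$PD) / use$total
  if (stats::var(frac) == 0 || stats::var(use$total) == 0)
    return(list(slope = 0, p_value = NA_real_, n_taxa = nrow(use),
                flag = "degenerate"))
  fit <- stats::lm(frac ~ total, data = data.frame(frac, total = use$total))
  co <- summary(fit)$coefficients
  list(slope = co["total", "Estimate"],
       p_value = co["total", "Pr(>|t|)"],
       n_taxa = nrow(use), flag = "ok")
}

#' Phylum-level interaction summaries
#'
#' Aggregates the per-taxon connectedness records by phylum: counts of
#' positive/negative interactions in the dependent and independent roles,
#' the number of observed (modelled) genera, the per-genus mean
#' connectedness (counts divided by the number of genera), and the
#' abundance-normalized connectedness — counts divided by the phylum's mean
#' relative abundance (a fraction), which rescales rare phyla upward so a
#' phylum at 1 percent abundance with the same count as one at 50 percent
#' scores 50 times higher.
#'
#' @param records output of [connectedness()].
#' @param taxonomy a `taxonomy_map` with phylum for every modelled taxon.
#' @param table the `processed_table` the network was fitted on (supplies
#'   relative abundances).
#' @return data.frame, one row per phylum.
#' @export
phylum_summaries <- function(records, taxonomy, table) {
  phy <- taxonomy_for(taxonomy, records$taxon)$phylum
  rel <- table$rel_abund[, records$taxon, drop = FALSE]
  out <- lapply(split(seq_along(phy), phy), function(ix) {
    counts <- c(PI = sum(records$PI[ix]), PD = sum(records$PD[ix]),
                NI = sum(records$NI[ix]), ND = sum(records$ND[ix]))
    total <- sum(counts)
    mean_abund <- mean(rowSums(rel[, ix, drop = FALSE]))
    data.frame(phylum = phy[ix[1L]],
               n_genera_observed = length(ix),
               positive = counts[["PI"]] + counts[["PD"]],
               negative = counts[["NI"]] + counts[["ND"]],
               PI = counts[["PI"]], PD = counts[["PD"]],
               NI = counts[["NI"]], ND = counts[["ND"]],
               total = total,
               mean_per_genus = total / length(ix),
               mean_rel_abundance = mean_abund,
               abund_norm_PI = counts[["PI"]] / mean_abund,
               abund_norm_PD = counts[["PD"]] / mean_abund,
               abund_norm_NI = counts[["NI"]] / mean_abund,
               abund_norm_ND = counts[["ND"]] / mean_abund)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Do phyla differ in mean number of positive interactions per genus?
#'
#' One-way linear model (ANOVA F-test) of the per-genus positive
#' interaction count on phylum membership.
#'
#' @param records output of [connectedness()].
#' @param taxonomy a `taxonomy_map`.
#' @return list with `p_value` (omnibus F), `means` (named per-phylum
#'   means), `flag` ("ok", "single_phylum" or "no_residual_df").
#' @export
phylum_positive_mean_test <- function(records, taxonomy) {
  phy <- factor(taxonomy_for(taxonomy, records$taxon)$phylum)
  pos <- records$PI + records$PD
  means <- tapply(pos, phy, mean)
  if (nlevels(phy) < 2L)
    return(list(p_value = NA_real_, means = means, flag = "single_phylum"))
  if (length(pos) - nlevels(phy) < 1L)
    return(list(p_value = NA_real_, means = means, flag = "no_residual_df"))
  fit <- stats::aov(pos ~ phy)
  p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  list(p_value = p, means = means, flag = "ok")
}

#' Shannon diversity (natural log)
#'
#' H = -sum p log p over the positive entries of a relative-abundance
#' vector, in nats. Non-normalized input is renormalized with a warning.
#'
#' @param p numeric vector of fractions (non-negative).
#' @return Shannon index in nats.
#' @export
shannon <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0))
  s <- sum(p)
  if (s <= 0) stop("all-zero abundance vector")
  if (abs(s - 1) > 1e-8) {
    warning("abundances do not sum to 1; renormalizing")
    p <- p / s
  }
  as.numeric(vegan::diversity(matrix(p, nrow = 1), index = "shannon"))
}

#' Relationship between a phylum's abundance and community diversity
#'
#' Between-individual mode regresses each individual's mean Shannon index
#' on the natural log of the individual's mean relative abundance of the
#' focal phylum (one point per individual). Within-individual mode fits the
#' same regression across samples inside each individual. On the log scale
#' a keystone-like phylum shows a strong positive linear relationship.
#'
#' @param tables list of `processed_table`s, one per individual.
#' @param taxonomy a `taxonomy_map` covering the modelled taxa.
#' @param phylum focal phylum name.
#' @param mode `"between"` or `"within"`.
#' @return For `"between"`: list with `slope`, `r_squared`, `p_value`,
#'   `n`, `flag`. For `"within"`: list of such lists, one per individual.
#' @export
diversity_abundance_model <- function(tables, taxonomy, phylum,
                                      mode = c("between", "within")) {
  mode <- match.arg(mode)
  phylum_abund <- function(pt) {
    phy <- taxonomy_for(taxonomy, pt$taxa_ids)$phylum
    rowSums(pt$rel_abund[, phy == phylum, drop = FALSE])
  }
  fit_one <- function(h, a, min_n) {
    ok <- a > 0
    if (sum(ok) < min_n)
      return(list(slope = NA_real_, r_squared = NA_real_,
                  p_value = NA_real_, n = sum(ok), flag = "insufficient_data"))
    fit <- stats::lm(h[ok] ~ log(a[ok]))
    sm <- summary(fit)
    list(slope = stats::coef(fit)[[2L]], r_squared = sm$r.squared,
         p_value = sm$coefficients[2L, 4L], n = sum(ok), flag = "ok")
  }
  if (mode == "between") {
    if (length(tables) < 3L)
      return(list(slope = NA_real_, r_squared = NA_real_,
                  p_value = NA_real_, n = length(tables),
                  flag = "insufficient_data"))
    h <- vapply(tables, function(pt)
      mean(apply(pt$rel_abund, 1L, shannon)), numeric(1))
    a <- vapply(tables, function(pt) mean(phylum_abund(pt)), numeric(1))
    if (all(a == 0))
      return(list(slope = NA_real_, r_squared = NA_real_,
                  p_value = NA_real_, n = length(tables),
                  flag = "phylum_absent"))
    fit_one(h, a, min_n = 3L)
  } else {
    lapply(tables, function(pt) {
      h <- apply(pt$rel_abund, 1L, shannon)
      a <- phylum_abund(pt)
      if (all(a == 0))
        return(list(slope = NA_real_, r_squared = NA_real_,
                    p_value = NA_real_, n = 0L, flag = "phylum_absent"))
      fit_one(h, a, min_n = 30L)
    })
  }
}
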