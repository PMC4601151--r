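#' Keep one sample per day (largest library)
#'
#' When several samples were collected on the same day, only the one with
#' the largest library size is kept. Ties are broken deterministically in
#' favour of the first occurrence in input order.
#'
#' @param table a [count_table()].
#' @return A [count_table()] with exactly one sample per day.
#' @export
dedup_daily <- function(table) {
  stopifnot(inherits(table, "count_table"))
  keep <- logical(length(table$sample_day))
  for (d in unique(table$sample_day)) {
    idx <- which(table$sample_day == d)
    keep[idx[which.max(table$library_size[idx])]] <- TRUE
  }
  subset_samples(table, keep)
}

#' Remove singleton taxa
#'
#' Drops taxa whose total count across the whole dataset equals one — the
#' standard definition of a singleton (a single read in the entire study).
#'
#' @param table a [count_table()] of raw counts.
#' @return Filtered [count_table()].
#' @export
remove_singletons <- function(table) {
  stopifnot(inherits(table, "count_table"))
  subset_taxa(table, colSums(table$counts) != 1)
}

#' Remove shallow samples
#'
#' Samples sequenced to fewer than `min_reads` reads are removed. The
#' boundary is a strict less-than: a sample at exactly `min_reads` is kept.
#'
#' @param table a [count_table()].
#' @param min_reads minimum library size (default 20000 reads).
#' @return Filtered [count_table()].
#' @export
filter_library_size <- function(table, min_reads = 20000) {
  stopifnot(inherits(table, "count_table"))
  keep <- table$library_size >= min_reads
  if (!any(keep))
    stop(sprintf(
      "all %d samples fall below the %g-read library threshold (max observed %g)",
      length(keep), min_reads, max(table$library_size)))
  subset_samples(table, keep)
}

#' Common scaling of libraries
#'
#' Every count in a sample is multiplied by the ratio of the smallest
#' library size in the dataset to that sample's library size, so that all
#' row sums equal the smallest library. This is the expectation-preserving
#' replacement for rarefying: it is the library scaling one would get by
#' averaging infinitely many random sub-samplings. Scaled counts are kept
#' as reals (no re-rounding).
#'
#' @param table a [count_table()].
#' @return A [count_table()] with scaled counts; the per-sample factors are
#'   attached as attribute `scaling_factor` and `library_size` keeps the raw
#'   (pre-scaling) sizes.
#' @export
common_scaling <- function(table) {
  stopifnot(inherits(table, "count_table"))
  fac <- min(table$library_size) / table$library_size
  out <- table
  out$counts <- table$counts * fac
  attr(out, "scaling_factor") <- stats::setNames(fac, table$sample_ids)
  out
}

#' Collapse taxa to the genus level
#'
#' Taxa sharing the same lineage path down to genus are merged by summing
#' their counts. Taxa with an empty genus label are grouped under their
#' finest named rank and labelled `unclassified-<rank>-<name>`, keeping them
#' distinct from named genera (and from unclassified groups of other
#' lineages).
#'
#' @param table a [count_table()].
#' @param taxonomy a `taxonomy_map` resolving every taxon in `table`.
#' @return A genus-level [count_table()]; the collapsed lineage of each new
#'   taxon is attached as attribute `taxonomy` (a `taxonomy_map`).
#' @export
collapse_genus <- function(table, taxonomy) {
  stopifnot(inherits(table, "count_table"))
  lin <- taxonomy_for(taxonomy, table$taxa_ids)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  label <- character(nrow(lin))
  for (r in seq_len(nrow(lin))) {
    if (nzchar(lin$genus[r])) {
      label[r] <- lin$genus[r]
    } else {
      named <- which(nzchar(unlist(lin[r, ranks])))
      if (!length(named)) {
        label[r] <- "unclassified-root"
      } else {
        finest <- ranks[max(named)]
        label[r] <- paste0("unclassified-", finest, "-", lin[[finest]][r])
      }
    }
  }
  key <- apply(lin[, ranks], 1L, paste, collapse = "|")
  groups <- split(seq_along(key), key)
  # one display label per path; disambiguate homonymous genera across paths
  glabel <- vapply(groups, function(ix) label[ix[1L]], character(1))
  glabel <- make.unique(glabel, sep = "_")
  merged <- vapply(groups, function(ix)
    rowSums(table$counts[, ix, drop = FALSE]),
    numeric(nrow(table$counts)))
  merged <- matrix(merged, nrow = nrow(table$counts),
                   dimnames = list(table$sample_ids, glabel))
  out <- count_table(merged, table$sample_day,
                     library_size = table$library_size)
  first <- vapply(groups, `[`, integer(1), 1L)
  coll <- lin[first, , drop = FALSE]
  coll$taxon_id <- glabel
  coll$genus <- glabel            # collapsed unit is addressed by its label
  rownames(coll) <- NULL
  class(coll) <- c("taxonomy_map", "data.frame")
  attr(out, "taxonomy") <- coll
  attr(out, "scaling_factor") <- attr(table, "scaling_factor")
  out
}

#' Remove rare taxa by mean relative abundance
#'
#' A taxon is dropped when its mean relative abundance — computed per sample
#' as count over sample total, then averaged unweighted over samples — falls
#' below `min_frac` (default 1e-4, i.e. 0.01 %).
#'
#' @param table a [count_table()].
#' @param min_frac minimum mean relative abundance (fraction).
#' @return Filtered [count_table()].
#' @export
filter_mean_abundance <- function(table, min_frac = 1e-4) {
  stopifnot(inherits(table, "count_table"))
  rel <- table$counts / rowSums(table$counts)
  subset_taxa(table, colMeans(rel) >= min_frac)
}

#' Log relative abundances with explicit missingness
#'
#' Relative abundances are renormalized over the retained taxa; the natural
#' log is applied to positive entries only, and zero counts are flagged as
#' missing (`NA`), never as `-Inf`. Only these non-missing points enter the
#' regression models downstream.
#'
#' @param table a [count_table()] after preprocessing.
#' @return A `processed_table`: list with the count table fields plus
#'   `rel_abund`, `log_abund` (NA where the count is zero) and
#'   `scaling_factor`.
#' @export
to_log_relative <- function(table) {
  stopifnot(inherits(table, "count_table"))
  tot <- rowSums(table$counts)
  if (any(tot <= 0))
    stop("sample(s) with all-zero counts: ",
         paste(table$sample_ids[tot <= 0], collapse = ", "))
  rel <- table$counts / tot
  lg <- ifelse(rel > 0, log(rel), NA_real_)
  structure(
    list(counts = table$counts,
         rel_abund = rel,
         log_abund = lg,
         sample_day = table$sample_day,
         library_size = table$library_size,
         sample_ids = table$sample_ids,
         taxa_ids = table$taxa_ids,
         scaling_factor = attr(table, "scaling_factor"),
         taxonomy = attr(table, "taxonomy")),
    class = "processed_table")
}

#' @export
print.processed_table <- function(x, ...) {
  cat(sprintf("processed_table: %d samples x %d taxa (%.1f%% zero cells)\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts == 0)))
  invisible(x)
}

#' Default preprocessing configuration
#'
#' @return list of the preprocessing switches and thresholds: daily
#'   deduplication on, singleton removal on, 20000-read library floor,
#'   0.01 % mean-abundance floor.
#' @export
preprocess_config <- function(dedup = TRUE, remove_singletons = TRUE,
                              min_reads = 20000, min_mean_frac = 1e-4) {
  list(dedup = dedup, remove_singletons = remove_singletons,
       min_reads = min_reads, min_mean_frac = min_mean_frac)
}

#' Run the full preprocessing cascade
#'
#' Applies, in order: (1) daily deduplication keeping the largest library,
#' (2) singleton removal, (3) the library-size floor, (4) common scaling,
#' (5) genus-level collapsing, (6) the mean relative-abundance floor — and
#' finally the log relative-abundance transform. Per-step retention counts
#' are recorded so the filter cascade is auditable.
#'
#' @param table raw [count_table()].
#' @param taxonomy a `taxonomy_map` covering all taxa.
#' @param config see [preprocess_config()].
#' @return A `processed_table`; element `retention` is a data.frame of
#'   samples/taxa retained after each step.
#' @export
run_preprocess <- function(table, taxonomy, config = preprocess_config()) {
  stopifnot(inherits(table, "count_table"))
  log <- list()
  note <- function(step, tb)
    data.frame(step = step, n_samples = nrow(tb$counts),
               n_taxa = ncol(tb$counts))
  log[["input"]] <- note("input", table)
  if (isTRUE(config$dedup)) table <- dedup_daily(table)
  log[["dedup_daily"]] <- note("dedup_daily", table)
  if (isTRUE(config$remove_singletons)) table <- remove_singletons(table)
  log[["remove_singletons"]] <- note("remove_singletons", table)
  table <- filter_library_size(table, config$min_reads %||% 0)
  log[["filter_library_size"]] <- note("filter_library_size", table)
  table <- common_scaling(table)
  table <- collapse_genus(table, taxonomy)
  log[["collapse_genus"]] <- note("collapse_genus", table)
  table <- filter_mean_abundance(table, config$min_mean_frac %||% 0)
  log[["filter_mean_abundance"]] <- note("filter_mean_abundance", table)
  tax <- attr(table, "taxonomy")
  tax <- tax[tax$taxon_id %in% table$taxa_ids, , drop = FALSE]
  attr(table, "taxonomy") <- tax
  out <- to_log_relative(table)
  out$retention <- do.call(rbind, c(log, list(make.row.names = FALSE)))
  out
}

#' Build a processed table directly from log-abundance series
#'
#' Wraps an already-transformed samples x taxa matrix of log abundances as
#' a `processed_table`, bypassing the count-level preprocessing. Intended
#' for feeding externally transformed (or simulated latent) series straight
#' into the regression machinery. `NA` cells mark missing observations.
#' The stored `rel_abund` is exp of the input and is only meaningful up to
#' a per-sample scale.
#'
#' @param log_abund numeric matrix, samples x taxa, natural-log scale.
#' @param sample_day integer day per sample (default 1..n).
#' @return a `processed_table`.
#' @export
processed_table_from_log <- function(log_abund,
                                     sample_day = seq_len(nrow(log_abund))) {
  log_abund <- as.matrix(log_abund)
  if (is.null(colnames(log_abund)))
    colnames(log_abund) <- paste0("T", seq_len(ncol(log_abund)))
  if (is.null(rownames(log_abund)))
    rownames(log_abund) <- paste0("S", seq_len(nrow(log_abund)))
  counts <- exp(log_abund)
  counts[is.na(counts)] <- 0
  structure(
    list(counts = counts,
         rel_abund = counts,
         log_abund = log_abund,
         sample_day = as.integer(sample_day),
         library_size = rep(1, nrow(log_abund)),
         sample_ids = rownames(log_abund),
         taxa_ids = colnames(log_abund),
         scaling_factor = NULL, taxonomy = NULL),
    class = "processed_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_samples <- function(table, keep) {
  ct <- count_table(table$counts[keep, , drop = FALSE],
                    table$sample_day[keep],
                    library_size = table$library_size[keep])
  attr(ct, "taxonomy") <- attr(table, "taxonomy")
  attr(ct, "scaling_factor") <- attr(table, "scaling_factor")[keep]
  ct
}

subset_taxa <- function(table, keep) {
  ct <- count_table(table$counts[, keep, drop = FALSE],
                    table$sample_day,
                    library_size = table$library_size)
  tax <- attr(table, "taxonomy")
  if (!is.null(tax))
    attr(ct, "taxonomy") <- tax[keep, , drop = FALSE]
  attr(ct, "scaling_factor") <- attr(table, "scaling_factor")
  ct
}
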