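#' Default end-to-end run configuration
#'
#' Collects every threshold of the standard workflow in one place: the
#' 20,000-read library floor, 0.01 percent mean-abundance floor, 50
#' percent prevalence floor, 50-point model floor, significance at
#' p <= 0.01, the subsampling ladder 250..25 with 100 replicates, and the
#' enterotyping settings. A frozen copy of the resolved configuration is
#' written with every run.
#'
#' @param ... named overrides of individual entries.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    min_reads = 20000,
    min_mean_frac = 1e-4,
    min_prev = 0.5,
    min_points = 50,
    alpha_level = 0.01,
    dedup = TRUE,
    remove_singletons = TRUE,
    subsample_levels = c(250, 200, 150, 125, 100, 75, 50, 25),
    subsample_reps = 100,
    run_robustness = FALSE,
    k_range = 2:10,
    sil_threshold = 0.25,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML or JSON
#' @param path configuration file; keys override [default_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  over <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_run_config, over)
}

#' Run the full analysis workflow
#'
#' Preprocess -> interaction inference -> network characterization
#' (categories, connectedness, phylum summaries) -> limiting-similarity
#' and co-occurrence tests -> enterotyping, writing all outputs plus a
#' JSON manifest (package version, seed, configuration, input hashes)
#' under `out_dir`. Subsampling robustness is optional
#' (`run_robustness = TRUE`) since it refits the system hundreds of times.
#'
#' @param table raw [count_table()] (or a path handled upstream).
#' @param taxonomy a `taxonomy_map`.
#' @param out_dir output directory (created if needed).
#' @param config a `run_config`.
#' @return invisibly, a list with all intermediate results.
#' @export
run_all <- function(table, taxonomy, out_dir,
                    config = default_run_config()) {
  stopifnot(inherits(table, "count_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  set.seed(config$seed)
  pre <- stage("preprocess", run_preprocess(
    table, taxonomy,
    preprocess_config(dedup = config$dedup,
                      remove_singletons = config$remove_singletons,
                      min_reads = config$min_reads,
                      min_mean_frac = config$min_mean_frac)))
  icfg <- inference_config(min_prev = config$min_prev,
                           min_points = config$min_points,
                           alpha_level = config$alpha_level)
  net <- stage("infer", infer_network(pre, icfg))
  tax <- pre$taxonomy
  cats <- stage("network", classify_pairs(net))
  prev <- category_prevalence(cats)
  conn <- connectedness(net, tax)
  phyl <- phylum_summaries(conn, tax, pre)
  tests <- stage("tests", list(
    limiting_similarity_with_diag =
      limiting_similarity_test(net, tax, include_diagonal = TRUE),
    limiting_similarity_no_diag =
      limiting_similarity_test(net, tax, include_diagonal = FALSE),
    positive_ratio = positive_ratio_test(conn),
    phylum_positive_mean = phylum_positive_mean_test(conn, tax),
    npoints_vs_significance = npoints_vs_significance(net)))
  cooc <- stage("cooccur", cooccurrence_matrix(pre, icfg))
  tests$cooccurrence_vs_beta <- cooccurrence_vs_beta(cooc, net)
  robust <- NULL
  if (isTRUE(config$run_robustness))
    robust <- stage("robustness", subsample_robustness(
      pre, config$subsample_levels, reps = config$subsample_reps,
      seed = config$seed, config = icfg))
  ent <- stage("enterotype", enterotype_pipeline(
    pre, enterotype_config(k_range = config$k_range,
                           sil_threshold = config$sil_threshold)))

  # outputs
  p <- function(f) file.path(out_dir, f)
  write_interaction_matrix(net, p("beta.tsv"), p("beta.masked.tsv"))
  .write_matrix_tsv(net$p, p("p_values.tsv"))
  .write_matrix_tsv(net$n_points, p("n_points.tsv"))
  utils::write.table(conn, p("connectedness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cats, p("pair_categories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(phyl, p("phylum_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_matrix_tsv(cooc, p("cooccurrence.tsv"))
  utils::write.table(ent$label_series, p("enterotype_series.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(robust))
    utils::write.table(robust, p("robustness.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tests, p("tests.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  manifest <- list(
    package = "gutdyn",
    version = as.character(utils::packageVersion("gutdyn")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    n_samples_in = nrow(table$counts),
    n_taxa_in = ncol(table$counts),
    n_taxa_modelled = length(net$taxa))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  jsonlite::write_json(unclass(config), p("config.frozen.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(preprocessed = pre, network = net, categories = cats,
                 category_prevalence = prev, connectedness = conn,
                 phylum_summary = phyl, tests = tests,
                 cooccurrence = cooc, robustness = robust,
                 enterotype = ent, config = config))
}

#' Tabular modelling report
#'
#' One row per analysed dataset with the classic summary columns —
#' maximum model size, number of significant interactions, significant
#' intra-genus models, negative:positive ratio, percent of the n^2
#' possible interactions — plus category prevalences and the most
#' connected taxa.
#'
#' @param results a result list from [run_all()], or a list of them
#'   (named by dataset).
#' @return data.frame, one row per dataset.
#' @export
report <- function(results) {
  if (!is.null(results$network)) results <- list(dataset = results)
  rows <- lapply(names(results), function(nm) {
    res <- results[[nm]]
    s <- res$network$summary
    conn <- res$connectedness
    top <- paste(conn$taxon[order(-conn$total)][1:min(3L, nrow(conn))],
                 collapse = ", ")
    fr <- res$category_prevalence$fractions
    gv <- function(x) if (x %in% names(fr)) fr[[x]] else NA_real_
    data.frame(
      dataset = nm,
      max_points = s$max_points,
      n_significant = s$n_significant,
      n_intra_significant = s$n_intra_significant,
      neg_pos_ratio = s$neg_pos_ratio,
      pct_of_possible = s$pct_of_possible,
      frac_cooperation = gv("cooperation"),
      frac_competition = gv("competition"),
      frac_exploitation = gv("exploitation"),
      frac_commensalism = gv("commensalism"),
      frac_amensalism = gv("amensalism"),
      top_connected = top)
  })
  do.call(rbind, rows)
}
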