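#' Construct a longitudinal community count table
#'
#' The central data container of the package: a samples x taxa matrix of
#' counts together with the integer collection day and the library size
#' (raw row sum) of every sample. Raw counts are integers; after common
#' scaling the cells are non-negative reals.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns. Row and
#'   column names are used as sample and taxon identifiers.
#' @param sample_day integer vector, collection day of each sample (days
#'   since study start).
#' @param library_size optional numeric vector of per-sample library sizes;
#'   defaults to the row sums of `counts`.
#' @return An object of class `count_table` with elements `counts`,
#'   `sample_day`, `library_size`, `sample_ids`, `taxa_ids`.
#' @export
count_table <- function(counts, sample_day, library_size = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("count table must contain at least one sample and one taxon")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("T", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids")
  if (length(sample_day) != nrow(counts))
    stop("sample_day must have one entry per sample")
  if (any(is.na(sample_day)))
    stop("every sample needs a collection day")
  sample_day <- as.integer(sample_day)
  if (is.null(library_size)) library_size <- rowSums(counts)
  if (length(library_size) != nrow(counts) || any(library_size <= 0))
    stop("library_size must be positive, one entry per sample")
  structure(
    list(counts = counts,
         sample_day = sample_day,
         library_size = as.numeric(library_size),
         sample_ids = rownames(counts),
         taxa_ids = colnames(counts)),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, days %d..%d\n",
              nrow(x$counts), ncol(x$counts),
              min(x$sample_day), max(x$sample_day)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table with sample-day metadata
#'
#' TSV layout: first column holds taxon ids, header row holds sample ids,
#' cells are counts (on-disk orientation is taxa x samples; it is transposed
#' so that downstream code always sees samples x taxa). BIOM support targets
#' the JSON dialect via the biomformat package. A metadata sidecar (TSV with
#' columns `sample_id` and `day`) supplies the collection day.
#'
#' @param path path to the count table.
#' @param meta_path path to the metadata TSV (`sample_id`, `day`).
#' @param format `"tsv"` or `"biom-json"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, meta_path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count table not found: ", path)
  if (format == "tsv") {
    first <- readLines(path, n = 10L)
    first <- first[!startsWith(first, "#")][1L]
    hdr <- strsplit(first, "\t", fixed = TRUE)[[1L]][-1L]
    if (anyDuplicated(hdr))
      stop("duplicate sample id in count table: ", path)
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, comment.char = "#",
                             colClasses = "character")
    if (nrow(raw) == 0L || ncol(raw) < 2L)
      stop("empty or malformed count table: ", path)
    taxa <- raw[[1L]]
    mat <- as.matrix(raw[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(mat), nrow = nrow(mat),
                                   dimnames = dimnames(mat)))
    if (any(is.na(num)))
      stop("non-numeric cell in count table: ", path)
    if (any(num < 0))
      stop("negative cell in count table: ", path)
    if (anyDuplicated(colnames(num)))
      stop("duplicate sample id in count table: ", path)
    counts <- t(num)                      # -> samples x taxa
    colnames(counts) <- taxa
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat is required for biom-json input")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")   # taxa x samples
    counts <- t(m)
  }
  meta <- read_sample_metadata(meta_path)
  missing <- setdiff(rownames(counts), meta$sample_id)
  if (length(missing))
    stop("samples missing day metadata: ", paste(missing, collapse = ", "))
  day <- meta$day[match(rownames(counts), meta$sample_id)]
  count_table(counts, sample_day = day)
}

#' Read a sample metadata table (sample_id, day)
#' @param path TSV path with columns `sample_id` and `day`.
#' @return data.frame with character `sample_id` and integer `day`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "day")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns sample_id and day")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id in metadata")
  meta$sample_id <- as.character(meta$sample_id)
  meta$day <- as.integer(meta$day)
  meta
}

#' Write a count table and its metadata sidecar
#'
#' Inverse of [read_count_table()]: taxa x samples TSV plus a
#' `sample_id`/`day` metadata TSV.
#'
#' @param table a [count_table()].
#' @param path output TSV path for the counts.
#' @param meta_path output TSV path for the metadata.
#' @export
write_count_table <- function(table, path, meta_path) {
  stopifnot(inherits(table, "count_table"))
  out <- data.frame(taxon_id = table$taxa_ids,
                    t(table$counts), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = table$sample_ids, day = table$sample_day)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.lineage_ranks <- c(kingdom = "k", phylum = "p", class = "c",
                    order = "o", family = "f", genus = "g")

#' Parse a Greengenes-style lineage string
#'
#' Accepts the usual `"k__Bacteria; p__Bacteroidetes; ...; g__Bacteroides"`
#' form, with or without whitespace after the separators. A missing suffix
#' (e.g. `g__`) yields an empty label at that rank; ranks absent from the
#' string are also empty.
#'
#' @param text lineage string.
#' @return Named character vector with elements kingdom, phylum, class,
#'   order, family, genus.
#' @export
parse_lineage <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- stats::setNames(rep("", length(.lineage_ranks)),
                         names(.lineage_ranks))
  fields <- strsplit(text, ";", fixed = TRUE)[[1L]]
  fields <- trimws(fields)
  fields <- fields[nzchar(fields)]
  for (f in fields) {
    if (!grepl("^[a-z]__", f))
      stop("unrecognized lineage field: '", f, "'")
    prefix <- substr(f, 1L, 1L)
    rank <- names(.lineage_ranks)[match(prefix, .lineage_ranks)]
    if (is.na(rank))
      stop("unrecognized rank prefix: '", prefix, "__'")
    out[[rank]] <- trimws(substring(f, 4L))
  }
  out
}

#' Read a taxonomy table mapping taxon ids to lineages
#'
#' TSV with columns `taxon_id` and `lineage` (Greengenes-style string).
#'
#' @param path TSV path.
#' @return A `taxonomy_map`: data.frame with taxon_id plus one column per
#'   rank (kingdom..genus).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "lineage") %in% names(raw)))
    stop("taxonomy table must have columns taxon_id and lineage")
  taxonomy_map(raw$taxon_id, raw$lineage)
}

#' Build a taxonomy map from taxon ids and lineage strings
#' @param taxon_id character vector of taxon identifiers.
#' @param lineage character vector of Greengenes-style lineage strings.
#' @return data.frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(taxon_id, lineage) {
  stopifnot(length(taxon_id) == length(lineage))
  parsed <- t(vapply(lineage, parse_lineage,
                     character(length(.lineage_ranks))))
  out <- data.frame(taxon_id = as.character(taxon_id), parsed,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Look up lineages for a set of taxa, erroring on unresolved ids
#' @keywords internal
taxonomy_for <- function(taxonomy, taxa) {
  idx <- match(taxa, taxonomy$taxon_id)
  if (anyNA(idx))
    stop("taxa missing from taxonomy: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  taxonomy[idx, , drop = FALSE]
}

#' Write interaction matrices (coefficients plus significance mask)
#'
#' Serializes the slope matrix of an inferred interaction network. Rows are
#' the dependent taxon i (acted upon), columns the independent taxon j
#' (acting) — stated in a header comment of every file. A companion "masked"
#' file carries beta only where the model was significant, `NA` elsewhere.
#'
#' @param network an `interaction_network` (see [infer_network()]).
#' @param path output TSV for the full beta matrix.
#' @param masked_path output TSV for the significance-masked matrix;
#'   default `path` with a `.masked.tsv` suffix.
#' @export
write_interaction_matrix <- function(network, path,
                                     masked_path = sub("\\.tsv$", "", path)) {
  stopifnot(inherits(network, "interaction_network"))
  if (masked_path == sub("\\.tsv$", "", path))
    masked_path <- paste0(masked_path, ".masked.tsv")
  .write_matrix_tsv(network$beta, path)
  masked <- network$beta
  masked[!(network$significant %in% TRUE)] <- NA_real_
  .write_matrix_tsv(masked, masked_path)
  invisible(c(path, masked_path))
}

.write_matrix_tsv <- function(mat, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ok <- tryCatch({
    writeLines("# rows: dependent taxon i (acted upon); columns: independent taxon j (acting)",
               con)
    header <- paste(c("taxon_id", colnames(mat)), collapse = "\t")
    writeLines(header, con)
    for (r in seq_len(nrow(mat))) {
      cells <- format(mat[r, ], digits = 15, trim = TRUE, scientific = NA)
      cells[is.na(mat[r, ])] <- "NA"
      writeLines(paste(c(rownames(mat)[r], cells), collapse = "\t"), con)
    }
    TRUE
  }, error = function(e) stop("cannot write matrix to ", path, ": ",
                              conditionMessage(e)))
  invisible(ok)
}

#' Read a matrix written by [write_interaction_matrix()]
#' @param path TSV path.
#' @return numeric matrix with row and column names.
#' @export
read_interaction_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- raw[[1L]]
  storage.mode(mat) <- "double"
  mat
}
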