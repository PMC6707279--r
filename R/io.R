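# Readers and writers for the external formats the pipeline touches:
# expression TSV (genes x samples), survival tables, GMT gene-set
# collections, IHC score tables and drug-response tables.  All loaders
# validate on entry and never reorder rows or columns.

#' Validate a genes-by-samples expression matrix
#'
#' Enforces the invariants every downstream statistic assumes: unique
#' uppercase gene symbols as row names, unique sample identifiers as column
#' names, and a fully finite numeric body (missing values are rejected, not
#' imputed).  Values are expected on a log-like scale, e.g. log2(x + 1) of
#' TPM or RSEM estimates.
#'
#' @param values numeric matrix, genes in rows, samples in columns; row and
#'   column names required.
#' @return the validated matrix, with gene symbols uppercased.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("ak4", "AK1"), paste0("S", 1:3)))
#' rownames(expression_matrix(m))
#' @export
expression_matrix <- function(values) {
  assert_that(is.matrix(values) && is.numeric(values),
              "expression values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "expression matrix needs gene row names and sample column names")
  rownames(values) <- toupper(rownames(values))
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  assert_that(length(dup_g) == 0L,
              "duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  assert_that(length(dup_s) == 0L,
              "duplicate sample ids: ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(values))
    stop_input(sprintf(
      "non-finite expression value at gene '%s', sample '%s' (%d offending cells); missing values are rejected, not imputed",
      rownames(values)[idx[1L]], colnames(values)[idx[2L]], length(bad)))
  }
  values
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects tab-separated text with gene symbols in the first column and one
#' header row of sample identifiers (the usual RSEM/TPM export layout).
#' Lines starting with `#` are treated as comments.  Gene symbols are
#' uppercased; duplicated genes or samples, and any non-numeric or missing
#' cell, are errors.  Row and column order is preserved exactly.
#'
#' @param path path to the TSV file.
#' @return numeric matrix (genes x samples), validated by
#'   [expression_matrix()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  assert_that(ncol(df) >= 2L, "expression file needs a gene column plus >= 1 sample column: ", path)
  genes <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(genes, colnames(body)))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(vals))
    stop_input(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                       idx[1L], genes[idx[1L]], colnames(vals)[idx[2L]]))
  }
  expression_matrix(vals)
}

#' Write an expression matrix as TSV
#'
#' Emits the layout [read_expression()] reads back: a commented provenance
#' line, a header of sample ids over a `gene` column, genes in rows.
#' `write_expression()` then `read_expression()` is the identity (row and
#' column order included).
#'
#' @param mat validated expression matrix.
#' @param path output path.
#' @param params optional character vector of `key=value` strings recorded in
#'   the comment line.
#' @export
write_expression <- function(mat, path, params = character()) {
  mat <- expression_matrix(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_result_tsv(df, path, params)
}

#' Validate a survival table
#'
#' A survival table has one record per sample: a unique `sample` id, a
#' strictly positive follow-up `time` in months, and an `event` indicator
#' (1 = death/event, 0 = censored).
#'
#' @param df data frame with columns `sample`, `time`, `event`.
#' @return the validated data frame (columns coerced, order preserved).
#' @export
survival_table <- function(df) {
  assert_that(all(c("sample", "time", "event") %in% names(df)),
              "survival table needs columns sample, time, event")
  out <- data.frame(sample = as.character(df$sample),
                    time = as.numeric(df$time),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  assert_that(!anyNA(out$time) && !anyNA(out$event), "missing time/event values")
  assert_that(all(out$time > 0), "follow-up times must be strictly positive")
  assert_that(all(out$event %in% c(0L, 1L)), "event indicator must be 0 or 1")
  dup <- unique(out$sample[duplicated(out$sample)])
  assert_that(length(dup) == 0L,
              "duplicate sample ids in survival table: ",
              paste(dup, collapse = ", "))
  out
}

# sniff the delimiter of a header line: tab wins over comma
.detect_sep <- function(path) {
  first <- readLines(path, n = 25L)
  first <- first[!startsWith(first, "#")]
  assert_that(length(first) > 0L, "empty file: ", path)
  if (grepl("\t", first[1L], fixed = TRUE)) "\t" else ","
}

.match_column <- function(nms, want) {
  hit <- which(tolower(nms) == want)
  assert_that(length(hit) == 1L, "need exactly one '", want,
              "' column, found ", length(hit))
  hit
}

#' Read a survival table from delimited text
#'
#' Accepts tab- or comma-separated text (auto-detected) with header columns
#' `sample`, `time` (months) and `event` (0/1), matched case-insensitively.
#' Records with a missing time or event, or a non-positive time, are dropped
#' with a counted warning; an event value outside \{0, 1\} is an error, as is
#' a file with zero usable records.
#'
#' @param path path to the file.
#' @return validated survival data frame (see [survival_table()]).
#' @export
read_survival <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  i_s <- .match_column(names(df), "sample")
  i_t <- .match_column(names(df), "time")
  i_e <- .match_column(names(df), "event")
  tm <- suppressWarnings(as.numeric(df[[i_t]]))
  ev_raw <- df[[i_e]]
  ev <- suppressWarnings(as.numeric(ev_raw))
  bad_event <- !is.na(ev) & !(ev %in% c(0, 1))
  assert_that(!any(bad_event), "event values outside {0,1}: ",
              paste(unique(ev_raw[bad_event]), collapse = ", "))
  usable <- !is.na(tm) & !is.na(ev) & tm > 0
  n_drop <- sum(!usable)
  if (n_drop > 0)
    warning(sprintf("dropped %d record(s) with missing or non-positive time/event", n_drop),
            call. = FALSE)
  assert_that(any(usable), "no usable survival records in ", path)
  survival_table(data.frame(sample = df[[i_s]][usable], time = tm[usable],
                            event = ev[usable], stringsAsFactors = FALSE))
}

#' Write a survival table as TSV
#' @param surv validated survival table.
#' @inheritParams write_expression
#' @export
write_survival <- function(surv, path, params = character()) {
  write_result_tsv(survival_table(surv), path, params)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then one or more member gene
#' symbols, tab-separated (the MSigDB dialect).  Member symbols are
#' uppercased; duplicate set names are an error; an empty file yields an
#' empty collection.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of member symbols, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- list()
    attr(out, "description") <- character()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  assert_that(length(short) == 0L,
              "GMT line(s) with fewer than 3 fields: line ",
              paste(short, collapse = ", "))
  nms <- vapply(parts, `[[`, "", 1L)
  dup <- unique(nms[duplicated(nms)])
  assert_that(length(dup) == 0L, "duplicate gene-set names: ",
              paste(dup, collapse = ", "))
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  empty <- which(lengths(sets) == 0L)
  assert_that(length(empty) == 0L, "gene set with no members on line ",
              paste(empty, collapse = ", "))
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection in GMT format
#' @param collection named list of member vectors as from [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description") %||%
    stats::setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Validate an IHC score table
#'
#' Immunohistochemistry staining scores: one record per (sample, marker)
#' pair, score integral in 0..3 (0 no staining, 1 weak, 2 moderate,
#' 3 strong).
#'
#' @param df data frame with columns `sample`, `marker`, `score`.
#' @return validated data frame.
#' @export
ihc_table <- function(df) {
  assert_that(all(c("sample", "marker", "score") %in% names(df)),
              "IHC table needs columns sample, marker, score")
  out <- data.frame(sample = as.character(df$sample),
                    marker = toupper(as.character(df$marker)),
                    score = as.numeric(df$score),
                    stringsAsFactors = FALSE)
  assert_that(!anyNA(out$score) && all(out$score == round(out$score)) &&
                all(out$score >= 0 & out$score <= 3),
              "IHC scores must be integers in 0..3")
  out$score <- as.integer(out$score)
  key <- paste(out$sample, out$marker, sep = "\r")
  dup <- unique(key[duplicated(key)])
  assert_that(length(dup) == 0L, "duplicate (sample, marker) pairs: ",
              paste(gsub("\r", "/", dup), collapse = ", "))
  out
}

#' Read an IHC score table from delimited text
#'
#' Tab- or comma-separated (auto-detected), header columns `sample`,
#' `marker`, `score` matched case-insensitively.
#' @param path path to the file.
#' @return validated IHC data frame.
#' @export
read_ihc <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ihc_table(data.frame(sample = df[[.match_column(names(df), "sample")]],
                       marker = df[[.match_column(names(df), "marker")]],
                       score = df[[.match_column(names(df), "score")]],
                       stringsAsFactors = FALSE))
}

#' Write an IHC score table as TSV
#' @param ihc validated IHC table.
#' @inheritParams write_expression
#' @export
write_ihc <- function(ihc, path, params = character()) {
  write_result_tsv(ihc_table(ihc), path, params)
}

#' Read a drug-response table from delimited text
#'
#' Per cell line and drug, the area under the dose-response curve (AUC;
#' higher = more resistant).  Columns `cell_line`, `drug` and a response
#' column (default `auc`) matched case-insensitively; (cell line, drug)
#' pairs must be unique and responses finite and non-negative.
#'
#' @param path path to the file.
#' @param metric name of the response column (default `"auc"`; set e.g.
#'   `"ic50"` for IC50 exports).
#' @return data frame with columns `cell_line`, `drug`, `auc`.
#' @export
read_drug_response <- function(path, metric = "auc") {
  assert_that(file.exists(path), "no such file: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  out <- data.frame(
    cell_line = as.character(df[[.match_column(names(df), "cell_line")]]),
    drug = as.character(df[[.match_column(names(df), "drug")]]),
    auc = as.numeric(df[[.match_column(names(df), tolower(metric))]]),
    stringsAsFactors = FALSE)
  assert_that(all(is.finite(out$auc)) && all(out$auc >= 0),
              "drug responses must be finite and non-negative")
  key <- paste(out$cell_line, out$drug, sep = "\r")
  dup <- unique(key[duplicated(key)])
  assert_that(length(dup) == 0L, "duplicate (cell_line, drug) pairs: ",
              paste(gsub("\r", "/", dup), collapse = ", "))
  out
}
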