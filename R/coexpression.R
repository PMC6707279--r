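# Seed-gene co-expression signatures: correlate one gene against the rest
# of the matrix and keep everything beyond a +/-0.3 Pearson cutoff.

#' Pearson product-moment correlation with validation
#'
#' Plain Pearson r, but with the preconditions the signature pipeline
#' relies on made explicit: at least 3 paired observations and nonzero
#' variance in both vectors (a zero-variance vector has no defined
#' correlation and is an error — callers drop such genes rather than
#' assigning r = 0).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 3L, "need at least 3 paired observations")
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "inputs must be finite")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "undefined correlation: zero-variance input")
  stats::cor(x, y)
}

# descending r, ties broken by gene symbol ascending
.order_by_r <- function(df) df[order(-df$r, df$gene), , drop = FALSE]

#' Correlate a seed gene against every other gene
#'
#' Computes the Pearson correlation of the seed gene's expression with each
#' remaining gene across all samples and returns the genes ranked by
#' descending r (ties broken by symbol).  Zero-variance genes have no
#' defined correlation and are excluded with a message giving the count.
#'
#' @param mat validated expression matrix (genes x samples).
#' @param seed_gene gene symbol present in `mat` (matched after
#'   uppercasing).
#' @return data frame with columns `gene`, `r`, one row per non-seed gene
#'   with a defined correlation.
#' @export
correlate_seed <- function(mat, seed_gene) {
  mat <- expression_matrix(mat)
  seed_gene <- toupper(seed_gene)
  assert_that(seed_gene %in% rownames(mat),
              "seed gene '", seed_gene, "' not found in matrix")
  sv <- mat[seed_gene, ]
  assert_that(stats::sd(sv) > 0, "seed gene '", seed_gene,
              "' has zero variance")
  others <- mat[setdiff(rownames(mat), seed_gene), , drop = FALSE]
  sds <- apply(others, 1L, stats::sd)
  n_const <- sum(sds == 0)
  if (n_const > 0)
    message(sprintf("dropped %d zero-variance gene(s) from correlation", n_const))
  others <- others[sds > 0, , drop = FALSE]
  r <- drop(stats::cor(t(others), sv))
  .order_by_r(data.frame(gene = rownames(others), r = unname(r),
                         stringsAsFactors = FALSE))
}

#' Extract a co-expression signature at a correlation cutoff
#'
#' Keeps the genes whose |r| reaches the cutoff.  The boundary |r| = cutoff
#' is included by default; `strict = TRUE` switches to the strict
#' inequality (|r| > cutoff).  An empty signature is legal.
#'
#' @param ranked data frame (`gene`, `r`) as from [correlate_seed()].
#' @param seed_gene the seed the ranking came from (recorded in the
#'   signature).
#' @param cutoff positive correlation cutoff in (0, 1]; default 0.3.
#' @param strict logical; if `TRUE`, require |r| strictly above the cutoff.
#' @return object of class `coexpression_signature`: a list with `seed`,
#'   `cutoff`, `strict` and `members` (data frame `gene`, `r`, ordered by
#'   descending r, ties by symbol).
#' @export
extract_signature <- function(ranked, seed_gene, cutoff = 0.3,
                              strict = FALSE) {
  assert_that(all(c("gene", "r") %in% names(ranked)),
              "ranked must have columns gene, r")
  assert_that(cutoff > 0 && cutoff <= 1, "cutoff must lie in (0, 1]")
  seed_gene <- toupper(seed_gene)
  keep <- if (strict) abs(ranked$r) > cutoff else abs(ranked$r) >= cutoff
  members <- .order_by_r(ranked[keep & ranked$gene != seed_gene, ,
                                drop = FALSE])
  rownames(members) <- NULL
  structure(list(seed = seed_gene, cutoff = cutoff, strict = strict,
                 members = members),
            class = "coexpression_signature")
}

#' Derive a seed gene's co-expression signature in one step
#'
#' Convenience composition of [correlate_seed()] and [extract_signature()].
#'
#' @inheritParams correlate_seed
#' @inheritParams extract_signature
#' @return a `coexpression_signature`.
#' @export
coexpression_signature <- function(mat, seed_gene, cutoff = 0.3,
                                   strict = FALSE) {
  extract_signature(correlate_seed(mat, seed_gene), seed_gene,
                    cutoff = cutoff, strict = strict)
}

#' Positively / negatively correlated arm of a signature
#' @param sig a `coexpression_signature`.
#' @return data frame of members with r > 0 (`positive_arm`) or r < 0
#'   (`negative_arm`).
#' @export
positive_arm <- function(sig) {
  stopifnot(inherits(sig, "coexpression_signature"))
  sig$members[sig$members$r > 0, , drop = FALSE]
}

#' @rdname positive_arm
#' @export
negative_arm <- function(sig) {
  stopifnot(inherits(sig, "coexpression_signature"))
  sig$members[sig$members$r < 0, , drop = FALSE]
}

#' @export
print.coexpression_signature <- function(x, ...) {
  cat(sprintf(
    "co-expression signature of %s: %d genes at |r| %s %.3g (%d positive, %d negative)\n",
    x$seed, nrow(x$members), if (x$strict) ">" else ">=", x$cutoff,
    nrow(positive_arm(x)), nrow(negative_arm(x))))
  invisible(x)
}

#' Write a co-expression signature as TSV
#' @param sig a `coexpression_signature`.
#' @inheritParams write_expression
#' @export
write_signature <- function(sig, path, params = character()) {
  stopifnot(inherits(sig, "coexpression_signature"))
  df <- sig$members
  df$arm <- ifelse(df$r > 0, "positive", "negative")
  write_result_tsv(df, path,
                   c(sprintf("seed=%s", sig$seed),
                     sprintf("cutoff=%g", sig$cutoff),
                     sprintf("strict=%s", sig$strict), params))
}
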