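# Expression versus drug-response correlation across cell lines, with
# discordant-line flagging.

# overlap of a named expression vector with one drug's response records
.drug_overlap <- function(values, responses, drug) {
  assert_that(!is.null(names(values)), "expression values must be named by cell line")
  assert_that(all(c("cell_line", "drug", "auc") %in% names(responses)),
              "responses needs columns cell_line, drug, auc")
  sub <- responses[responses$drug == drug, , drop = FALSE]
  assert_that(nrow(sub) > 0L, "no response records for drug '", drug, "'")
  common <- intersect(names(values), sub$cell_line)
  n_drop <- (length(values) - length(common)) + (nrow(sub) - length(common))
  if (n_drop > 0)
    message(sprintf("dropped %d cell line(s) without both expression and response",
                    n_drop))
  assert_that(length(common) >= 4L,
              "need >= 4 overlapping cell lines, got ", length(common))
  data.frame(cell_line = common, expr = unname(values[common]),
             auc = sub$auc[match(common, sub$cell_line)],
             stringsAsFactors = FALSE)
}

#' Correlate gene expression with drug response across cell lines
#'
#' Pearson or Spearman correlation between a gene's expression and the AUC
#' of one drug over the cell lines present in both inputs.  A negative r
#' means higher expression tracks greater drug sensitivity (lower AUC).
#'
#' @param values named numeric vector of per-cell-line expression.
#' @param responses drug-response table ([read_drug_response()]).
#' @param drug drug name to select from the table.
#' @param method `"pearson"` (two-sided t-approximation p) or
#'   `"spearman"`.
#' @return list: `r`, `p`, `n`, `method`, `drug`.
#' @export
correlate_drug <- function(values, responses, drug,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  d <- .drug_overlap(values, responses, drug)
  ct <- suppressWarnings(stats::cor.test(d$expr, d$auc, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d),
       method = method, drug = drug)
}

#' Flag cell lines discordant with the expression-response trend
#'
#' Fits the least-squares line of AUC on expression over the overlapping
#' cell lines and flags lines whose standardized residual exceeds 2 in
#' magnitude — e.g. a line with high transcript expression but an
#' unexpectedly sensitive (or resistant) response.
#'
#' @inheritParams correlate_drug
#' @return data frame: `cell_line`, `expr`, `auc`, `residual`,
#'   `std_residual`, `flagged`.
#' @export
flag_outlier_lines <- function(values, responses, drug) {
  d <- .drug_overlap(values, responses, drug)
  fit <- stats::lm(auc ~ expr, data = d)
  std <- stats::rstandard(fit)
  # (near-)exact linear fits leave only rounding noise in the residuals;
  # standardizing by a sigma at machine precision is meaningless
  if (stats::sigma(fit) < 1e-8 * max(stats::sd(d$auc), 1e-300)) std[] <- 0
  std[!is.finite(std)] <- 0
  out <- data.frame(cell_line = d$cell_line, expr = d$expr, auc = d$auc,
                    residual = unname(stats::residuals(fit)),
                    std_residual = unname(std),
                    flagged = abs(unname(std)) > 2,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$std_residual)), , drop = FALSE] |>
    (\(x) { rownames(x) <- NULL; x })()
}
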