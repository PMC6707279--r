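# Signed two-seed consensus signature: the symbol intersection of two
# seeds' prognostic signature members, each gene carrying its correlation
# to both seeds and its survival z.

#' Intersect two seeds' prognostic gene sets into a consensus signature
#'
#' Takes the prognostic members of two co-expression signatures (as from
#' [prognostic_members()]) and forms their plain gene-symbol intersection.
#' The intersection is not sign-constrained: a gene positively correlated
#' with one seed and negatively with the other is retained, and the
#' (sign r_a, sign r_b) pattern is reported so users can filter.  The two
#' inputs must come from the same survival scoring run, so a shared gene
#' with conflicting z values is an error.
#'
#' @param prog_a,prog_b data frames (`gene`, `r`, `z`) of prognostic
#'   members for seeds a and b; both must be nonempty.
#' @param seed_a,seed_b seed gene symbols, recorded in the result.
#' @return object of class `consensus_signature`: list with `seed_a`,
#'   `seed_b`, `genes` (data frame `gene`, `r_to_a`, `r_to_b`, `z`,
#'   `direction`) and `provenance` (`n_a`, `n_b`, `n_intersect`,
#'   `n_union`).
#' @export
intersect_signatures <- function(prog_a, prog_b, seed_a = "A", seed_b = "B") {
  for (p in list(prog_a, prog_b))
    assert_that(is.data.frame(p) && all(c("gene", "r", "z") %in% names(p)) &&
                  nrow(p) >= 1L,
                "prognostic sets must be nonempty data frames with gene, r, z")
  shared <- intersect(prog_a$gene, prog_b$gene)
  ia <- match(shared, prog_a$gene)
  ib <- match(shared, prog_b$gene)
  if (length(shared)) {
    dz <- abs(prog_a$z[ia] - prog_b$z[ib])
    bad <- shared[dz > 1e-8]
    assert_that(length(bad) == 0L,
                "conflicting z for shared gene(s) (inputs from different scoring runs?): ",
                paste(utils::head(bad, 5L), collapse = ", "))
  }
  n_a <- nrow(prog_a); n_b <- nrow(prog_b); n_i <- length(shared)
  n_union <- length(union(prog_a$gene, prog_b$gene))
  stopifnot(n_union == n_a + n_b - n_i)  # inclusion-exclusion conservation
  genes <- data.frame(gene = shared,
                      r_to_a = prog_a$r[ia], r_to_b = prog_b$r[ib],
                      z = prog_a$z[ia], stringsAsFactors = FALSE)
  genes$direction <- ifelse(genes$z > 0, "adverse", "protective")
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(seed_a = toupper(seed_a), seed_b = toupper(seed_b),
                 genes = genes,
                 provenance = c(n_a = n_a, n_b = n_b, n_intersect = n_i,
                                n_union = n_union)),
            class = "consensus_signature")
}

#' Annotate a consensus signature with direction and sign patterns
#'
#' Labels every gene `adverse` (z > 0) or `protective` (z < 0) and adds the
#' (sign of r to seed a, sign of r to seed b) pattern, e.g. `"+/-"` for a
#' gene co-expressed with seed a but anti-correlated with seed b.  A
#' summary table of pattern counts is attached as the `pattern_summary`
#' attribute of the `genes` element.
#'
#' @param consensus a nonempty `consensus_signature`.
#' @return the consensus with `direction` and `pattern` columns and the
#'   pattern summary attached.
#' @export
annotate_direction <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_signature"))
  g <- consensus$genes
  assert_that(nrow(g) >= 1L, "consensus signature is empty")
  g$direction <- ifelse(g$z > 0, "adverse", "protective")
  g$pattern <- paste0(ifelse(g$r_to_a > 0, "+", "-"), "/",
                      ifelse(g$r_to_b > 0, "+", "-"))
  tab <- table(factor(g$pattern, levels = c("+/+", "+/-", "-/+", "-/-")))
  attr(g, "pattern_summary") <- as.data.frame(tab,
                                              responseName = "n",
                                              stringsAsFactors = FALSE) |>
    stats::setNames(c("pattern", "n"))
  consensus$genes <- g
  consensus
}

#' Order consensus genes for heatmap display
#'
#' Returns the gene symbols sorted by descending correlation to the chosen
#' reference seed (ties broken by symbol), the deterministic ordering used
#' to lay out a consensus-signature expression heatmap.
#'
#' @param consensus a `consensus_signature`.
#' @param reference `"a"` or `"b"`: which seed's correlation to rank by.
#' @return character vector of gene symbols.
#' @export
order_for_heatmap <- function(consensus, reference = c("a", "b")) {
  stopifnot(inherits(consensus, "consensus_signature"))
  reference <- match.arg(reference)
  g <- consensus$genes
  r <- if (reference == "a") g$r_to_a else g$r_to_b
  g$gene[order(-r, g$gene)]
}

#' @export
print.consensus_signature <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "consensus signature %s/%s: %d genes (|A| = %d, |B| = %d, |A union B| = %d)\n",
    x$seed_a, x$seed_b, p[["n_intersect"]], p[["n_a"]], p[["n_b"]],
    p[["n_union"]]))
  if (nrow(x$genes))
    cat(sprintf("  %d adverse, %d protective\n",
                sum(x$genes$direction == "adverse"),
                sum(x$genes$direction == "protective")))
  invisible(x)
}

#' Write a consensus signature as TSV
#' @param consensus a `consensus_signature`.
#' @inheritParams write_expression
#' @export
write_consensus <- function(consensus, path, params = character()) {
  stopifnot(inherits(consensus, "consensus_signature"))
  cons <- if (nrow(consensus$genes) > 0 && is.null(consensus$genes$pattern))
    annotate_direction(consensus) else consensus
  p <- cons$provenance
  write_result_tsv(as.data.frame(cons$genes), path,
                   c(sprintf("seed_a=%s", cons$seed_a),
                     sprintf("seed_b=%s", cons$seed_b),
                     sprintf("venn=%d/%d/%d", p[["n_a"]], p[["n_b"]],
                             p[["n_intersect"]]), params))
}
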