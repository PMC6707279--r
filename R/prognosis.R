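# Per-gene survival scoring: univariate Cox proportional-hazards Wald z on
# standardized expression (Efron ties), the |z| > 2 prognostic rule, and
# signature-level prognostic-fraction profiles.

# align a named expression vector with a survival table; message the counts
# of samples present on only one side
.align_surv <- function(values, surv, quiet = FALSE) {
  assert_that(!is.null(names(values)), "expression values must be named by sample")
  common <- intersect(names(values), surv$sample)
  n_drop <- (length(values) - length(common)) +
    (nrow(surv) - length(common))
  if (n_drop > 0 && !quiet)
    message(sprintf("dropped %d sample(s) without both expression and survival",
                    n_drop))
  assert_that(length(common) >= 3L, "fewer than 3 samples with both expression and survival")
  i <- match(common, surv$sample)
  list(x = values[common], time = surv$time[i], event = surv$event[i])
}

# one univariate Cox fit on a standardized covariate; y is a Surv object
.cox_fit1 <- function(x, y, gene) {
  fit <- survival::coxph.fit(matrix(x, ncol = 1L), y, strata = NULL,
                             offset = NULL, init = 0,
                             control = survival::coxph.control(iter.max = 50),
                             weights = NULL, method = "efron",
                             rownames = NULL)
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1L]))
  if (!is.finite(beta) || !is.finite(se) || se <= 0)
    stop_input("Cox fit did not converge for gene '", gene, "'")
  z <- beta / se
  # monotone partial likelihood (perfect separation): beta drifts without
  # bound; |beta| > 10 per SD is beyond any plausible biology
  if (abs(beta) > 10) {
    warning(sprintf("monotone likelihood for gene '%s'; z clamped to %d",
                    gene, as.integer(sign(beta) * 37)), call. = FALSE)
    z <- sign(beta) * 37
  }
  c(beta = beta, se = se, z = z)
}

#' Univariate Cox survival z-score for one gene
#'
#' Standardizes the gene's expression to mean 0 / SD 1 over the samples
#' shared with the survival table, fits a univariate Cox
#' proportional-hazards model (Efron tie handling) and reports the Wald
#' z = beta / se.  Positive z means higher expression is adverse; negative
#' z means protective.  This is the single-cohort analogue of a
#' PRECOG-style survival z-score.
#'
#' @param values named numeric vector of expression, names = sample ids.
#' @param surv survival table ([survival_table()]); the sample
#'   intersection is used, dropped counts are messaged.
#' @param gene gene symbol recorded in the output.
#' @param quiet suppress the sample-alignment message.
#' @return one-row data frame: `gene`, `beta` (log hazard per SD), `se`,
#'   `z`, `hr`, `n_samples`, `n_events`.
#' @export
cox_z <- function(values, surv, gene = "gene", quiet = FALSE) {
  surv <- survival_table(surv)
  al <- .align_surv(values, surv, quiet = quiet)
  n_events <- sum(al$event)
  assert_that(n_events >= 2L, "need at least 2 events, got ", n_events)
  assert_that(stats::sd(al$x) > 0, "zero-variance expression for gene '",
              gene, "'")
  y <- survival::Surv(al$time, al$event)
  est <- .cox_fit1(as.vector(scale(al$x)), y, gene)
  data.frame(gene = toupper(gene), beta = est[["beta"]], se = est[["se"]],
             z = est[["z"]], hr = exp(est[["beta"]]),
             n_samples = length(al$x), n_events = n_events,
             stringsAsFactors = FALSE)
}

#' Univariate Cox survival z-scores for many genes
#'
#' Applies [cox_z()] to each requested gene of an expression matrix,
#' aligning samples once.  Zero-variance genes are dropped with a message;
#' a non-converging fit is an error naming the gene.
#'
#' @param mat validated expression matrix.
#' @param surv survival table.
#' @param genes gene symbols to score (default: all rows).
#' @return data frame, one row per scored gene, columns as in [cox_z()].
#' @export
cox_z_all <- function(mat, surv, genes = rownames(mat)) {
  mat <- expression_matrix(mat)
  surv <- survival_table(surv)
  genes <- toupper(genes)
  missing <- setdiff(genes, rownames(mat))
  assert_that(length(missing) == 0L, "genes not in matrix: ",
              paste(utils::head(missing, 5L), collapse = ", "))
  common <- intersect(colnames(mat), surv$sample)
  n_drop <- (ncol(mat) - length(common)) + (nrow(surv) - length(common))
  if (n_drop > 0)
    message(sprintf("dropped %d sample(s) without both expression and survival",
                    n_drop))
  assert_that(length(common) >= 3L, "fewer than 3 usable samples")
  i <- match(common, surv$sample)
  n_events <- sum(surv$event[i])
  assert_that(n_events >= 2L, "need at least 2 events, got ", n_events)
  sub <- mat[genes, common, drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0))
    message(sprintf("dropped %d zero-variance gene(s) from survival scoring",
                    sum(sds == 0)))
  keep <- genes[sds > 0]
  y <- survival::Surv(surv$time[i], surv$event[i])
  est <- vapply(keep, function(g) {
    .cox_fit1(as.vector(scale(sub[g, ])), y, g)
  }, c(beta = 0, se = 0, z = 0))
  out <- data.frame(gene = keep, beta = est["beta", ], se = est["se", ],
                    z = est["z", ], hr = exp(est["beta", ]),
                    n_samples = length(common), n_events = n_events,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag prognostic genes at a survival z-score threshold
#'
#' A gene is prognostic iff |z| is strictly greater than the threshold
#' (default 2); the sign of z labels it `adverse` (z > 0) or `protective`
#' (z < 0).  A Benjamini-Hochberg adjusted p-value column is appended for
#' information only; it plays no part in the flag.
#'
#' @param stats data frame of per-gene Cox statistics ([cox_z_all()]).
#' @param threshold positive z threshold; default 2.
#' @return `stats` with added columns `prognostic` (logical), `direction`
#'   (`"adverse"`/`"protective"`), `p` and `p_bh`.
#' @export
flag_prognostic <- function(stats, threshold = 2) {
  assert_that(threshold > 0, "threshold must be > 0")
  assert_that(all(c("gene", "z") %in% names(stats)),
              "stats must have columns gene, z")
  stats$prognostic <- abs(stats$z) > threshold
  stats$direction <- ifelse(stats$z > 0, "adverse", "protective")
  stats$p <- 2 * stats::pnorm(-abs(stats$z))
  stats$p_bh <- stats::p.adjust(stats$p, method = "BH")
  stats
}

#' Prognostic-fraction profile of a co-expression signature
#'
#' Joins a signature's members with flagged survival statistics and reports
#' how many members are prognostic, the percentage, and the four (sign of
#' r, sign of z) quadrant counts among the prognostic members — the
#' scatter-plot summary used to characterize whether genes co-expressed
#' with the seed are adverse or protective.
#'
#' @param sig a `coexpression_signature`.
#' @param flags output of [flag_prognostic()]; members without a flag are
#'   dropped with a message.
#' @return one-row data frame of class `signature_profile`: `seed`,
#'   `n_total`, `n_prognostic`, `percent`, `q_rpos_zpos`, `q_rpos_zneg`,
#'   `q_rneg_zpos`, `q_rneg_zneg`.
#' @export
prognostic_fraction <- function(sig, flags) {
  stopifnot(inherits(sig, "coexpression_signature"))
  assert_that(all(c("gene", "z", "prognostic") %in% names(flags)),
              "flags must come from flag_prognostic()")
  m <- merge(sig$members, flags[, c("gene", "z", "prognostic")],
             by = "gene", sort = FALSE)
  n_missing <- nrow(sig$members) - nrow(m)
  if (n_missing > 0)
    message(sprintf("dropped %d signature member(s) without survival statistics",
                    n_missing))
  n_total <- nrow(m)
  if (n_total == 0L) {
    warning("empty signature: prognostic fraction undefined, reported as 0",
            call. = FALSE)
    out <- data.frame(seed = sig$seed, n_total = 0L, n_prognostic = 0L,
                      percent = 0, q_rpos_zpos = 0L, q_rpos_zneg = 0L,
                      q_rneg_zpos = 0L, q_rneg_zneg = 0L,
                      stringsAsFactors = FALSE)
    class(out) <- c("signature_profile", "data.frame")
    return(out)
  }
  pr <- m[m$prognostic, , drop = FALSE]
  out <- data.frame(
    seed = sig$seed, n_total = n_total, n_prognostic = nrow(pr),
    percent = 100 * nrow(pr) / n_total,
    q_rpos_zpos = sum(pr$r > 0 & pr$z > 0),
    q_rpos_zneg = sum(pr$r > 0 & pr$z < 0),
    q_rneg_zpos = sum(pr$r < 0 & pr$z > 0),
    q_rneg_zneg = sum(pr$r < 0 & pr$z < 0),
    stringsAsFactors = FALSE)
  class(out) <- c("signature_profile", "data.frame")
  out
}

#' Rank signature profiles by prognostic percentage
#'
#' Stable descending sort on `percent`; ties broken by seed symbol
#' ascending.
#'
#' @param profiles a list of `signature_profile` rows or a data frame with
#'   columns `seed`, `percent`.
#' @return data frame of profiles in rank order, with a `rank` column.
#' @export
rank_signatures <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, profiles)
  assert_that(is.data.frame(profiles) && nrow(profiles) >= 1L,
              "need at least one signature profile")
  assert_that(all(c("seed", "percent") %in% names(profiles)),
              "profiles must have columns seed, percent")
  out <- profiles[order(-profiles$percent, profiles$seed), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Prognostic members of a signature, with correlation and z
#'
#' The curated per-seed gene set fed to the consensus construction: the
#' signature members flagged prognostic, each carrying its correlation to
#' the seed and its survival z.
#'
#' @inheritParams prognostic_fraction
#' @return data frame with columns `gene`, `r`, `z`.
#' @export
prognostic_members <- function(sig, flags) {
  stopifnot(inherits(sig, "coexpression_signature"))
  m <- merge(sig$members, flags[, c("gene", "z", "prognostic")],
             by = "gene", sort = FALSE)
  out <- m[m$prognostic, c("gene", "r", "z"), drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
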