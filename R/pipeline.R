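# End-to-end pipeline: simulate (or load) a cohort, derive both seed
# signatures, score survival, build the consensus, run enrichment and
# stratification, and write every artifact with a manifest.

#' Pipeline configuration
#'
#' One serializable source of truth for a full run.  Thresholds are
#' validated up front so a bad configuration fails before any stage runs.
#'
#' @param out_dir directory for all outputs (created if needed).
#' @param sim a [sim_config()] describing the cohort to simulate; ignored
#'   when `expression_path`/`survival_path` are supplied.
#' @param expression_path,survival_path optional paths to an existing
#'   cohort; both or neither.
#' @param gmt_path optional GMT collection for the enrichment stage; when
#'   `NULL` and the cohort is simulated, the planted modules are used as
#'   gene sets.
#' @param cutoff Pearson cutoff for signature extraction, in (0, 1].
#' @param strict use the strict |r| > cutoff rule.
#' @param z_threshold prognostic z threshold, > 0.
#' @param n_perm GSEA permutations (>= 100).
#' @param split expression dichotomization rule for stratification.
#' @param reference reference label for the combined-marker hazard ratio.
#' @param seed integer seed governing every stochastic stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            expression_path = NULL, survival_path = NULL,
                            gmt_path = NULL,
                            cutoff = 0.3, strict = FALSE,
                            z_threshold = 2, n_perm = 1000L,
                            split = "median",
                            reference = "a-low/b-high",
                            seed = 0L) {
  assert_that(cutoff > 0 && cutoff <= 1, "cutoff must lie in (0, 1]")
  assert_that(z_threshold > 0, "z_threshold must be > 0")
  assert_that(n_perm >= 100L, "n_perm must be >= 100")
  assert_that(split %in% c("median", "quantile", "value"),
              "split must be median, quantile or value")
  assert_that(is.null(expression_path) == is.null(survival_path),
              "supply expression_path and survival_path together")
  if (is.null(seed)) {
    seed <- 0L
    message("no seed supplied; defaulting to 0")
  }
  cfg <- list(out_dir = out_dir, sim = sim,
              expression_path = expression_path,
              survival_path = survival_path, gmt_path = gmt_path,
              cutoff = cutoff, strict = strict, z_threshold = z_threshold,
              n_perm = as.integer(n_perm), split = split,
              reference = reference, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full signature pipeline
#'
#' Chains simulate (or load) -> co-expression signatures for both seeds ->
#' per-gene Cox z -> consensus intersection -> pre-ranked GSEA ->
#' median-split stratification with combined-marker hazard ratios.  Every
#' stage writes a TSV under `config$out_dir`; reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return data frame manifest of class `pipeline_manifest`: `stage`,
#'   `artifact`, `path`, `n_rows`, `md5`.
#' @export
run_full <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, artifact, path, n_rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, artifact = artifact, path = path, n_rows = n_rows,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  pth <- function(f) file.path(config$out_dir, f)
  prm <- c(sprintf("seed=%d", config$seed),
           sprintf("cutoff=%g", config$cutoff),
           sprintf("z_threshold=%g", config$z_threshold))

  # stage 1: cohort
  if (is.null(config$expression_path)) {
    sim <- config$sim
    sim$rng_seed <- config$seed
    cohort <- generate_cohort(sim)
    expr <- cohort$expression
    surv <- cohort$survival
    seeds <- sim$seeds
    write_expression(expr, pth("expression.tsv"), prm)
    write_survival(surv, pth("survival.tsv"), prm)
    write_result_tsv(cohort$truth$genes, pth("ground_truth.tsv"), prm)
    note("simulate", "expression", pth("expression.tsv"), nrow(expr))
    note("simulate", "survival", pth("survival.tsv"), nrow(surv))
    note("simulate", "ground_truth", pth("ground_truth.tsv"),
         nrow(cohort$truth$genes))
  } else {
    cohort <- NULL
    expr <- read_expression(config$expression_path)
    surv <- read_survival(config$survival_path)
    seeds <- config$sim$seeds
  }

  # stage 2: co-expression signatures of the two seeds
  sig_a <- coexpression_signature(expr, seeds[1L], config$cutoff,
                                  config$strict)
  sig_b <- coexpression_signature(expr, seeds[2L], config$cutoff,
                                  config$strict)
  write_signature(sig_a, pth("signature_a.tsv"), prm)
  write_signature(sig_b, pth("signature_b.tsv"), prm)
  note("coexpress", "signature_a", pth("signature_a.tsv"),
       nrow(sig_a$members))
  note("coexpress", "signature_b", pth("signature_b.tsv"),
       nrow(sig_b$members))

  # stage 3: survival scoring over the union of signature members
  score_genes <- union(sig_a$members$gene, sig_b$members$gene)
  assert_that(length(score_genes) >= 1L,
              "both signatures empty at cutoff ", config$cutoff)
  stats_ <- flag_prognostic(cox_z_all(expr, surv, score_genes),
                            config$z_threshold)
  write_result_tsv(stats_, pth("prognosis.tsv"), prm)
  note("prognosis", "gene_stats", pth("prognosis.tsv"), nrow(stats_))

  # stage 4: consensus
  pa <- prognostic_members(sig_a, stats_)
  pb <- prognostic_members(sig_b, stats_)
  assert_that(nrow(pa) >= 1L && nrow(pb) >= 1L,
              "a prognostic set is empty; cannot build a consensus")
  cons <- annotate_direction(
    intersect_signatures(pa, pb, seeds[1L], seeds[2L]))
  write_consensus(cons, pth("consensus.tsv"), prm)
  note("consensus", "consensus", pth("consensus.tsv"), nrow(cons$genes))

  # stage 5: enrichment of the z-ranked consensus
  collection <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
  else if (!is.null(cohort)) {
    tg <- cohort$truth$genes
    sets <- split(tg$gene, tg$module)
    sets <- sets[!(names(sets) %in% c("SEED", "NOISE"))]
    attr(sets, "description") <- stats::setNames(
      rep("planted module", length(sets)), names(sets))
    sets
  } else NULL
  if (!is.null(collection) && length(collection) > 0 &&
      nrow(cons$genes) >= 2L) {
    gsea <- tryCatch(
      preranked_gsea(consensus_ranking(cons), collection,
                     n_perm = config$n_perm, rng_seed = config$seed),
      error = function(e) {
        message("enrichment stage skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(gsea)) {
      write_result_tsv(gsea, pth("gsea.tsv"), prm)
      note("gsea", "enrichment", pth("gsea.tsv"), nrow(gsea))
    }
  }

  # stage 6: stratification on the two seed genes (median split)
  st_a <- dichotomize_expression(expr[seeds[1L], ], seeds[1L], config$split)
  st_b <- dichotomize_expression(expr[seeds[2L], ], seeds[2L], config$split)
  combined <- combine_markers(st_a, st_b)
  lr <- logrank_test(surv, combined)
  hr <- tryCatch(cox_hr_groups(surv, combined, config$reference),
                 error = function(e) NULL)
  strat <- data.frame(quantity = c("logrank_chi2", "logrank_df", "logrank_p"),
                      value = c(lr$chi2, lr$df, lr$p),
                      stringsAsFactors = FALSE)
  if (!is.null(hr))
    strat <- rbind(strat,
                   data.frame(quantity = paste0("hr:", hr$label),
                              value = hr$hr, stringsAsFactors = FALSE))
  write_result_tsv(strat, pth("stratification.tsv"), prm)
  note("stratify", "summary", pth("stratification.tsv"), nrow(strat))

  out <- do.call(rbind, manifest)
  class(out) <- c("pipeline_manifest", "data.frame")
  out
}
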