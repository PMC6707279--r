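# Latent-factor cohort simulator.  Two anti-correlated seed genes each drive
# a co-expression module; a designated subset of module genes carries a
# proportional-hazards effect of consistent sign per module; optional decoy
# modules ride independent factors and carry no hazard.  This is the
# statistical structure the downstream analysis assumes, so every stage can
# be exercised and parameter recovery can be tested.

#' Simulation configuration for a synthetic survival cohort
#'
#' Describes a cohort of `n_samples` with two seed genes `seed_a`, `seed_b`
#' whose latent factors are jointly Gaussian with correlation
#' `seed_anticorrelation`.  Each seed drives a module of `module_sizes`
#' genes: gene g equals `sign_g * loading_g * factor + sqrt(1 - loading_g^2) *
#' noise`, so its population Pearson correlation with the seed is
#' `sign_g * loading_g`.  A fraction `hazard_frac` of each module's genes
#' carries a per-SD log-hazard `beta = hazard_beta * sign_g` (module A) or
#' `hazard_beta * sign_g` with the module's own `hazard_beta` (module B), so
#' a positive `hazard_beta` makes genes co-expressed with the seed adverse
#' and anti-correlated genes protective, and a negative one the reverse.
#' `n_decoy_modules` adds further seed + module blocks on independent
#' factors with no hazard, and `n_noise_genes` adds independent genes.
#'
#' Defaults emulate a TCGA lung-adenocarcinoma-like cohort: 521 samples,
#' seed anti-correlation -0.42, loadings 0.6 with half the module genes
#' negatively signed, adverse module A (`hazard_beta = 0.5`) and protective
#' module B (`hazard_beta = -0.5`), exponential baseline hazard of 0.014
#' events/month (median survival near 50 months), light independent
#' censoring and an administrative cutoff at 200 months of follow-up.
#'
#' @param n_samples number of patients.
#' @param seeds character(2), names of the two seed genes.
#' @param module_sizes integer(2), genes per seed module.
#' @param loadings numeric(2) in (0, 1], factor loading per module.
#' @param neg_fraction numeric(2) in [0, 1], fraction of module genes with
#'   negative sign (anti-correlated with their seed).
#' @param hazard_betas numeric(2), per-SD log-hazard attached to module
#'   genes; the per-gene beta is `hazard_beta * sign_g`.  0 = no hazard.
#' @param hazard_frac numeric(2) in [0, 1], fraction of each module's genes
#'   (the first ones, deterministically) that carry the hazard.
#' @param seed_anticorrelation correlation of the two seed factors, in
#'   [-1, 0].
#' @param n_decoy_modules number of extra no-hazard modules on independent
#'   factors; their seeds are named `DECOY1..`, members `DECOY1G001..`.
#' @param decoy_module_size,decoy_loading size and loading shared by decoy
#'   modules.
#' @param n_noise_genes independent standard-normal genes (`NOISE0001..`).
#' @param baseline_rate exponential baseline hazard, events per month.
#' @param censor_rate rate of the independent exponential censoring time
#'   (0 = administrative censoring only).
#' @param admin_cutoff administrative censoring time, months.
#' @param seed_noise_sd residual noise added to the seed-gene rows.
#' @param rng_seed integer seed making [generate_cohort()] reproducible.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 521L,
                       seeds = c("SEEDA", "SEEDB"),
                       module_sizes = c(50L, 50L),
                       loadings = c(0.6, 0.6),
                       neg_fraction = c(0.5, 0.5),
                       hazard_betas = c(0.5, -0.5),
                       hazard_frac = c(1, 1),
                       seed_anticorrelation = -0.42,
                       n_decoy_modules = 0L,
                       decoy_module_size = 50L,
                       decoy_loading = 0.6,
                       n_noise_genes = 200L,
                       baseline_rate = 0.014,
                       censor_rate = 0.01,
                       admin_cutoff = 200,
                       seed_noise_sd = 0.05,
                       rng_seed = 1L) {
  seeds <- toupper(seeds)
  assert_that(length(seeds) == 2L && !anyDuplicated(seeds),
              "exactly two distinct seed genes required")
  rep2 <- function(x) if (length(x) == 1L) rep(x, 2L) else x
  module_sizes <- as.integer(rep2(module_sizes))
  loadings <- rep2(loadings); neg_fraction <- rep2(neg_fraction)
  hazard_betas <- rep2(hazard_betas); hazard_frac <- rep2(hazard_frac)
  assert_that(all(loadings > 0 & loadings <= 1), "loadings must lie in (0, 1]")
  assert_that(all(neg_fraction >= 0 & neg_fraction <= 1) &&
                all(hazard_frac >= 0 & hazard_frac <= 1),
              "neg_fraction and hazard_frac must lie in [0, 1]")
  assert_that(seed_anticorrelation >= -1 && seed_anticorrelation <= 0,
              "seed_anticorrelation must lie in [-1, 0]")
  assert_that(baseline_rate > 0, "baseline_rate must be > 0")
  assert_that(admin_cutoff > 0, "admin_cutoff must be > 0")
  assert_that(censor_rate >= 0, "censor_rate must be >= 0")
  assert_that(n_samples >= 3L, "need at least 3 samples")
  assert_that(decoy_loading > 0 && decoy_loading <= 1,
              "decoy_loading must lie in (0, 1]")
  cfg <- list(n_samples = as.integer(n_samples), seeds = seeds,
              module_sizes = module_sizes, loadings = loadings,
              neg_fraction = neg_fraction, hazard_betas = hazard_betas,
              hazard_frac = hazard_frac,
              seed_anticorrelation = seed_anticorrelation,
              n_decoy_modules = as.integer(n_decoy_modules),
              decoy_module_size = as.integer(decoy_module_size),
              decoy_loading = decoy_loading,
              n_noise_genes = as.integer(n_noise_genes),
              baseline_rate = baseline_rate, censor_rate = censor_rate,
              admin_cutoff = admin_cutoff, seed_noise_sd = seed_noise_sd,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

# per-gene layout implied by a config: module membership, loading, sign, beta
.sim_gene_plan <- function(cfg) {
  plan <- list()
  add <- function(module, seed_gene, size, loading, negf, hbeta, hfrac) {
    if (size == 0L) return(NULL)
    genes <- sprintf("%sG%03d", module, seq_len(size))
    n_neg <- floor(size * negf)
    sgn <- rep(c(1, -1), c(size - n_neg, n_neg))
    n_haz <- floor(size * hfrac)
    beta <- ifelse(seq_len(size) <= n_haz, hbeta * sgn, 0)
    data.frame(gene = genes, module = module, seed_gene = seed_gene,
               loading = loading, sign = sgn, beta = beta,
               stringsAsFactors = FALSE)
  }
  plan[["A"]] <- add("MODA", cfg$seeds[1L], cfg$module_sizes[1L],
                     cfg$loadings[1L], cfg$neg_fraction[1L],
                     cfg$hazard_betas[1L], cfg$hazard_frac[1L])
  plan[["B"]] <- add("MODB", cfg$seeds[2L], cfg$module_sizes[2L],
                     cfg$loadings[2L], cfg$neg_fraction[2L],
                     cfg$hazard_betas[2L], cfg$hazard_frac[2L])
  if (cfg$n_decoy_modules > 0L) {
    for (d in seq_len(cfg$n_decoy_modules)) {
      nm <- sprintf("DECOY%d", d)
      plan[[nm]] <- add(nm, nm, cfg$decoy_module_size, cfg$decoy_loading,
                        0.5, 0, 1)
    }
  }
  do.call(rbind, plan)
}

#' Simulate proportional-hazards survival from a linear predictor
#'
#' Event times follow an exponential proportional-hazards model:
#' `T_i = -log(U_i) / (baseline_rate * exp(eta_i))`.  Censoring is the
#' minimum of an independent exponential time (rate `censor_rate`) and the
#' administrative cutoff; the recorded time is `min(T, C)` with
#' `event = [T <= C]`.
#'
#' @param eta numeric vector of per-sample log-hazard linear predictors;
#'   names, if present, become sample ids.
#' @param baseline_rate exponential baseline hazard (events/month), > 0.
#' @param censor_rate rate of the exponential censoring time; 0 disables
#'   random censoring.
#' @param admin_cutoff administrative cutoff in months.
#' @param rng_seed optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @return survival data frame (`sample`, `time`, `event`); warns if no
#'   events were generated.
#' @export
simulate_survival <- function(eta, baseline_rate, censor_rate = 0,
                              admin_cutoff = 200, rng_seed = NULL) {
  assert_that(all(is.finite(eta)), "eta must be finite")
  assert_that(baseline_rate > 0 && admin_cutoff > 0 && censor_rate >= 0,
              "invalid survival parameters")
  n <- length(eta)
  ids <- names(eta) %||% sprintf("S%04d", seq_len(n))
  with_seed(rng_seed, {
    t_event <- -log(stats::runif(n)) / (baseline_rate * exp(eta))
    t_cens <- if (censor_rate > 0)
      pmin(stats::rexp(n, censor_rate), admin_cutoff) else rep(admin_cutoff, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    if (all(event == 0L))
      warning("all samples censored; survival scoring needs >= 2 events",
              call. = FALSE)
    survival_table(data.frame(sample = ids, time = time, event = event,
                              stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic expression + survival cohort
#'
#' Draws the latent seed factors, builds seed, module, decoy and noise gene
#' rows, computes the per-sample linear predictor
#' `eta_i = sum_g beta_g x_gi` over the hazard-carrying genes, simulates
#' survival with [simulate_survival()], and finally shifts the expression
#' matrix by +8 (truncated at 0) so values resemble log2-scale abundances.
#' The shift is per-matrix affine, so planted correlations are untouched;
#' `eta` is computed on the pre-shift values.
#'
#' With a fixed `rng_seed` the output is bit-reproducible.
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_cohort` with elements `expression` (validated
#'   matrix), `survival` (survival table) and `truth` (list: `genes` with
#'   per-gene module/loading/sign/beta, `samples` with factor values and
#'   `eta`).
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  cfg <- config
  plan <- .sim_gene_plan(cfg)
  all_ids <- c(cfg$seeds,
               if (cfg$n_decoy_modules > 0L) sprintf("DECOY%d", seq_len(cfg$n_decoy_modules)),
               plan$gene,
               if (cfg$n_noise_genes > 0L) sprintf("NOISE%04d", seq_len(cfg$n_noise_genes)))
  assert_that(!anyDuplicated(all_ids),
              "module gene sets must be disjoint from each other and the seeds")
  with_seed(cfg$rng_seed, {
    n <- cfg$n_samples
    samples <- sprintf("S%04d", seq_len(n))
    rho <- cfg$seed_anticorrelation
    f_a <- stats::rnorm(n)
    f_b <- rho * f_a + sqrt(1 - rho^2) * stats::rnorm(n)
    factors <- cbind(f_a, f_b)
    colnames(factors) <- cfg$seeds
    if (cfg$n_decoy_modules > 0L) {
      dec <- matrix(stats::rnorm(n * cfg$n_decoy_modules), n)
      colnames(dec) <- sprintf("DECOY%d", seq_len(cfg$n_decoy_modules))
      factors <- cbind(factors, dec)
    }
    seed_names <- colnames(factors)
    # seed gene rows: their factor plus small measurement noise
    x_seed <- t(factors) +
      matrix(stats::rnorm(length(factors), sd = cfg$seed_noise_sd),
             ncol(factors), n)
    rownames(x_seed) <- seed_names
    # module gene rows from the factor model
    x_mod <- NULL
    if (!is.null(plan)) {
      fac_of <- factors[, plan$seed_gene, drop = FALSE]
      lam <- plan$loading * plan$sign
      eps <- matrix(stats::rnorm(nrow(plan) * n), nrow(plan), n)
      x_mod <- sweep(t(fac_of), 1L, lam, `*`) +
        sweep(eps, 1L, sqrt(1 - plan$loading^2), `*`)
      rownames(x_mod) <- plan$gene
    }
    x_noise <- NULL
    if (cfg$n_noise_genes > 0L) {
      x_noise <- matrix(stats::rnorm(cfg$n_noise_genes * n),
                        cfg$n_noise_genes, n)
      rownames(x_noise) <- sprintf("NOISE%04d", seq_len(cfg$n_noise_genes))
    }
    x <- rbind(x_seed, x_mod, x_noise)
    colnames(x) <- samples
    haz <- if (is.null(plan)) logical() else plan$beta != 0
    eta <- if (any(haz)) drop(crossprod(x_mod[haz, , drop = FALSE], plan$beta[haz]))
           else rep(0, n)
    names(eta) <- samples
    surv <- simulate_survival(eta, cfg$baseline_rate, cfg$censor_rate,
                              cfg$admin_cutoff, rng_seed = NULL)
    expr <- expression_matrix(pmax(x + 8, 0))
    truth_genes <- data.frame(
      gene = rownames(x),
      module = c(rep("SEED", length(seed_names)), plan$module,
                 rep("NOISE", cfg$n_noise_genes)),
      loading = c(rep(1, length(seed_names)), plan$loading,
                  rep(0, cfg$n_noise_genes)),
      sign = c(rep(1, length(seed_names)), plan$sign,
               rep(0, cfg$n_noise_genes)),
      beta = c(rep(0, length(seed_names)), plan$beta,
               rep(0, cfg$n_noise_genes)),
      stringsAsFactors = FALSE)
    truth_samples <- data.frame(sample = samples, factors,
                                eta = eta, stringsAsFactors = FALSE,
                                check.names = FALSE)
    out <- list(expression = expr, survival = surv,
                truth = list(genes = truth_genes, samples = truth_samples),
                config = cfg)
    class(out) <- "sim_cohort"
    out
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d samples, %d events / %d samples\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$survival$event), nrow(x$survival)))
  invisible(x)
}

#' Build a deterministic IHC score table from category counts
#'
#' Produces exactly the requested number of samples per (marker, score)
#' cell, with stable sample ids (`P001`, `P002`, ...) shared across markers
#' so two-marker analyses can join on sample.  Counts may be given per
#' score (`"0".."3"`) or per dichotomized category (`"0_1"`, `"2_3"`); a
#' lumped category is split as evenly as possible between its two scores.
#'
#' @param counts named list, one element per marker; each element a named
#'   numeric vector of non-negative integer counts.
#' @return validated IHC data frame; empty (0 rows) for all-zero counts.
#' @examples
#' generate_ihc_fixture(list(AK1 = c("0_1" = 58, "2_3" = 82)))
#' @export
generate_ihc_fixture <- function(counts) {
  assert_that(is.list(counts) && !is.null(names(counts)),
              "counts must be a named list (marker -> category counts)")
  rows <- lapply(names(counts), function(marker) {
    ct <- counts[[marker]]
    assert_that(!is.null(names(ct)) && all(ct >= 0) && all(ct == round(ct)),
                "counts for ", marker, " must be named non-negative integers")
    per_score <- integer(4L)
    for (nm in names(ct)) {
      k <- as.integer(ct[[nm]])
      if (nm %in% c("0", "1", "2", "3")) {
        i <- as.integer(nm) + 1L
        per_score[i] <- per_score[i] + k
      } else if (nm %in% c("0_1", "2_3")) {
        lo <- if (nm == "0_1") 1L else 3L
        per_score[lo] <- per_score[lo] + k %/% 2L
        per_score[lo + 1L] <- per_score[lo + 1L] + k - k %/% 2L
      } else stop_input("unknown score category '", nm, "' for ", marker)
    }
    n <- sum(per_score)
    if (n == 0L) return(NULL)
    data.frame(sample = sprintf("P%03d", seq_len(n)), marker = marker,
               score = rep(0:3, per_score), stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(ihc_table(data.frame(sample = character(), marker = character(),
                                score = integer())))
  ihc_table(do.call(rbind, rows))
}

#' Synthetic 140-patient two-marker IHC cohort
#'
#' A deterministic stand-in for a published (but private) lung
#' adenocarcinoma IHC series: 140 patients scored for AK1 and AK4, with the
#' reported marker prevalences — AK1 high (score 2-3) in 82/140 (58.6%) and
#' AK4 high in 74/140 (52.9%).  Only the category counts are reproduced;
#' per-patient scores are an arbitrary deterministic split and carry no
#' clinical information.
#'
#' @return validated IHC data frame with 280 rows (140 patients x 2
#'   markers).
#' @export
synthetic_ihc_cohort <- function() {
  generate_ihc_fixture(list(AK1 = c("0_1" = 58, "2_3" = 82),
                            AK4 = c("0_1" = 66, "2_3" = 74)))
}
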