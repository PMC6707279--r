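# Univariate Cox survival z-scores and signature prognostic profiles.

test_that("Newton Cox beta matches grid-search Efron partial likelihood on small fixtures", {
  for (fx in cox_small_fixtures()) {
    surv <- survival_table(data.frame(sample = paste0("s", seq_along(fx$time)),
                                      time = fx$time, event = fx$event))
    xs <- as.vector(scale(fx$x))
    st <- cox_z(setNames(fx$x, surv$sample), surv, "G", quiet = TRUE)
    beta_grid <- grid_cox_beta(fx$time, fx$event, xs)
    expect_lt(abs(st$beta - beta_grid), 1e-6)
    expect_equal(st$z, st$beta / st$se)
    expect_equal(st$hr, exp(st$beta))
  }
})

test_that("a monotone partial likelihood is flagged and z clamped", {
  # 6 samples, all events, expression equal to the time rank: perfect
  # separation, the partial likelihood increases without bound in -beta
  time <- 1:6; event <- rep(1L, 6); x <- as.numeric(1:6)
  surv <- survival_table(data.frame(sample = paste0("s", 1:6),
                                    time = time, event = event))
  w <- capture_warnings(st <- cox_z(setNames(x, surv$sample), surv, "G",
                                    quiet = TRUE))
  expect_true(any(grepl("monotone", w)))
  expect_identical(st$z, -37)
})

test_that("cox_z validates its inputs", {
  surv <- survival_table(data.frame(sample = paste0("s", 1:6),
                                    time = 1:6, event = rep(1L, 6)))
  expect_error(cox_z(setNames(rep(2, 6), surv$sample), surv, "G",
                     quiet = TRUE), "zero-variance")
  surv1 <- survival_table(data.frame(sample = paste0("s", 1:6), time = 1:6,
                                     event = c(1L, rep(0L, 5))))
  expect_error(cox_z(setNames(rnorm(6), surv1$sample), surv1, "G",
                     quiet = TRUE), "2 events")
})

test_that("z is invariant to positive rescaling and antisymmetric in sign flips", {
  set.seed(3)
  surv <- survival_table(data.frame(sample = paste0("s", 1:60),
                                    time = rexp(60, 0.1),
                                    event = rbinom(60, 1, 0.7)))
  x <- setNames(rnorm(60), surv$sample)
  z0 <- cox_z(x, surv, quiet = TRUE)$z
  expect_equal(cox_z(10 * x, surv, quiet = TRUE)$z, z0, tolerance = 1e-8)
  expect_equal(cox_z(-x, surv, quiet = TRUE)$z, -z0, tolerance = 1e-8)
})

test_that("misaligned samples are dropped with a message, not an error", {
  surv <- survival_table(data.frame(sample = paste0("s", 1:30),
                                    time = seq(1, 30), event = rep(1L, 30)))
  x <- setNames(rnorm(35), paste0("s", 6:40))
  expect_message(st <- cox_z(x, surv, "G"), "dropped 15 sample")
  expect_identical(st$n_samples, 25L)
})

test_that("the prognostic flag is strict at the threshold", {
  stats_ <- data.frame(gene = c("A", "B", "C"), z = c(2.0, -2.1, 2.1))
  fl <- flag_prognostic(stats_)
  expect_identical(fl$prognostic, c(FALSE, TRUE, TRUE))
  expect_identical(fl$direction, c("adverse", "protective", "adverse"))
  expect_true(all(fl$p_bh >= fl$p))                      # BH never shrinks p
  expect_true(all(diff(fl$p_bh[order(fl$p)]) >= 0))      # monotone in p
})

test_that("prognostic_fraction computes percent and quadrant counts", {
  sig <- extract_signature(
    data.frame(gene = sprintf("G%02d", 1:10),
               r = c(0.9, 0.8, 0.7, 0.6, 0.5, -0.5, -0.6, -0.7, -0.8, -0.9)),
    "SEED", cutoff = 0.3)
  flags <- flag_prognostic(
    data.frame(gene = sprintf("G%02d", 1:10),
               z = c(3, 2.5, 0.1, -0.2, 0.5, -1, 0.3, -2.6, -3.1, 1.2)))
  prof <- prognostic_fraction(sig, flags)
  expect_identical(prof$n_total, 10L)
  expect_identical(prof$n_prognostic, 4L)
  expect_equal(prof$percent, 40.0)
  expect_identical(c(prof$q_rpos_zpos, prof$q_rpos_zneg,
                     prof$q_rneg_zpos, prof$q_rneg_zneg),
                   c(2L, 0L, 0L, 2L))

  empty <- extract_signature(data.frame(gene = "G01", r = 0.1), "SEED")
  expect_warning(p0 <- prognostic_fraction(empty, flags), "empty")
  expect_identical(p0$n_total, 0L)
  expect_equal(p0$percent, 0)
})

test_that("rank_signatures sorts by percent with symbol tie-break", {
  profs <- data.frame(seed = c("C", "B", "A"), percent = c(10, 40, 40))
  rk <- rank_signatures(profs)
  expect_identical(rk$seed, c("A", "B", "C"))
  expect_identical(rk$rank, 1:3)
  one <- rank_signatures(data.frame(seed = "X", percent = 5))
  expect_identical(one$seed, "X")
})

test_that("hazard-bearing seed outranks a hazard-free seed in a planted cohort", {
  co <- generate_cohort(sim_config(n_samples = 1000, module_sizes = c(25, 25),
                                   loadings = c(0.6, 0.6),
                                   hazard_betas = c(0.5, 0),
                                   seed_anticorrelation = 0,
                                   n_noise_genes = 50, rng_seed = 23))
  sig_a <- coexpression_signature(co$expression, "SEEDA")
  sig_b <- coexpression_signature(co$expression, "SEEDB")
  st <- flag_prognostic(cox_z_all(co$expression, co$survival,
                                  union(sig_a$members$gene,
                                        sig_b$members$gene)))
  prof_a <- prognostic_fraction(sig_a, st)
  prof_b <- prognostic_fraction(sig_b, st)
  expect_gt(prof_a$percent, prof_b$percent)
})

test_that("null z-scores are standard normal (KS, 9/10 seeds)", {
  pass <- vapply(1:10, function(s) {
    co <- generate_cohort(sim_config(n_samples = 150, module_sizes = c(0, 0),
                                     n_noise_genes = 200, rng_seed = 100 + s))
    st <- cox_z_all(co$expression, co$survival,
                    co$truth$genes$gene[co$truth$genes$module == "NOISE"])
    stats::ks.test(st$z, pnorm)$p.value > 0.01
  }, TRUE)
  expect_gte(sum(pass), 9L)
})
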