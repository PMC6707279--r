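# Dichotomization, Kaplan-Meier, log-rank, combined markers, hazard ratios.

test_that("IHC dichotomization follows the score 2-3 = high rule", {
  ihc <- ihc_table(data.frame(sample = paste0("p", 1:4), marker = "AK1",
                              score = 0:3))
  st <- dichotomize_ihc(ihc, "AK1")
  expect_identical(st$level, c("low", "low", "high", "high"))
  fx <- dichotomize_ihc(synthetic_ihc_cohort(), "AK1")
  expect_identical(sum(fx$level == "high"), 82L)
  expect_identical(nrow(fx), 140L)
  expect_error(dichotomize_ihc(ihc, "MISSING"), "MISSING")
})

test_that("expression dichotomization splits at the median with ties to low", {
  v <- setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5))
  st <- dichotomize_expression(v, "G")
  expect_setequal(st$sample[st$level == "high"], c("s4", "s5"))
  expect_identical(st$level[st$sample == "s3"], "low")   # value == median

  flat <- setNames(rep(2, 4), paste0("s", 1:4))
  expect_warning(st0 <- dichotomize_expression(flat, "G"), "identical")
  expect_true(all(st0$level == "low"))

  set.seed(2)
  big <- setNames(rnorm(1000), sprintf("s%04d", 1:1000))
  stb <- dichotomize_expression(big, "G")
  expect_lte(abs(sum(stb$level == "high") - sum(stb$level == "low")), 1L)

  stq <- dichotomize_expression(v, "G", rule = "quantile", q = 0.8)
  expect_identical(sum(stq$level == "high"), 1L)
  stv <- dichotomize_expression(v, "G", rule = "value", value = 1.5)
  expect_identical(sum(stv$level == "high"), 4L)
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # 2 samples, events at t = 1, 2: S(1) = 0.5, S(2) = 0
  surv <- survival_table(data.frame(sample = c("a", "b"), time = c(1, 2),
                                    event = c(1, 1)))
  st <- data.frame(sample = c("a", "b"), level = "all")
  km <- km_estimate(surv, st)
  ev <- km$table[km$table$n_event > 0, ]
  expect_equal(ev$surv, c(0.5, 0))

  # 5-sample worked fixture: times 1..5, events 1,1,0,1,0
  surv5 <- survival_table(data.frame(sample = paste0("s", 1:5), time = 1:5,
                                     event = c(1, 1, 0, 1, 0)))
  km5 <- km_estimate(surv5, data.frame(sample = paste0("s", 1:5),
                                       level = "all"))
  ev5 <- km5$table[km5$table$n_event > 0, ]
  expect_equal(ev5$surv, c(4/5, 4/5 * 3/4, 4/5 * 3/4 * 1/2),
               tolerance = 1e-12)
  # non-increasing step function within [0, 1]
  expect_true(all(diff(km5$table$surv) <= 1e-12))
  expect_true(all(km5$table$surv >= 0 & km5$table$surv <= 1))

  # all-censored group is skipped with a warning
  surv_c <- survival_table(data.frame(sample = c("a", "b", "c", "d"),
                                      time = c(1, 2, 3, 4),
                                      event = c(1, 1, 0, 0)))
  st2 <- data.frame(sample = c("a", "b", "c", "d"),
                    level = c("g1", "g1", "g2", "g2"))
  expect_warning(km2 <- km_estimate(surv_c, st2), "g2")
  expect_true(all(km2$table$group == "g1"))
})

test_that("log-rank matches the direct observed-vs-expected formula", {
  set.seed(5)
  time <- c(rexp(30, 0.1), rexp(30, 0.25))
  event <- rbinom(60, 1, 0.8)
  surv <- survival_table(data.frame(sample = paste0("s", 1:60),
                                    time = time, event = event))
  st <- data.frame(sample = paste0("s", 1:60),
                   level = rep(c("g1", "g2"), each = 30))
  lr <- logrank_test(surv, st)
  expect_equal(lr$chi2, logrank_chi2_oracle(time, event, st$level),
               tolerance = 1e-8)
  expect_equal(lr$p, pchisq(lr$chi2, 1, lower.tail = FALSE))

  # identical groups: chi2 ~ 0
  surv_d <- survival_table(data.frame(sample = paste0("s", 1:20),
                                      time = rep(1:10, 2),
                                      event = rep(c(1, 0), 10)))
  st_d <- data.frame(sample = paste0("s", 1:20),
                     level = rep(c("g1", "g2"), each = 10))
  lr_d <- logrank_test(surv_d, st_d)
  expect_lt(lr_d$chi2, 1e-10)

  # relabeling invariance
  st_swap <- st
  st_swap$level <- ifelse(st$level == "g1", "g2", "g1")
  expect_equal(logrank_test(surv, st_swap)$chi2, lr$chi2, tolerance = 1e-12)

  expect_error(logrank_test(surv, data.frame(sample = paste0("s", 1:60),
                                             level = "only")),
               ">= 2 groups")
})

test_that("log-rank detects a true hazard ratio of 3 (power check)", {
  rej <- vapply(1:60, function(s) {
    surv <- simulate_survival(rep(c(0, log(3)), each = 200),
                              baseline_rate = 0.01, censor_rate = 0.005,
                              admin_cutoff = 200, rng_seed = 2000 + s)
    st <- data.frame(sample = surv$sample,
                     level = rep(c("lo", "hi"), each = 200))
    logrank_test(surv, st)$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.95)
})

test_that("combined markers form the four-cell cross product", {
  sa <- data.frame(sample = c("p1", "p2", "p3"), marker = "A",
                   level = c("high", "high", "low"))
  sb <- data.frame(sample = c("p1", "p2"), marker = "B",
                   level = c("low", "high"))
  expect_message(cm <- combine_markers(sa, sb), "1 record")
  expect_identical(cm$label[cm$sample == "p1"], "a-high/b-low")
  expect_identical(cm$label[cm$sample == "p2"], "a-high/b-high")
  expect_false("p3" %in% cm$sample)

  # independent 50/50 markers: each cell near n/4
  set.seed(6)
  ids <- sprintf("q%03d", 1:400)
  s1 <- data.frame(sample = ids, level = sample(c("high", "low"), 400, TRUE))
  s2 <- data.frame(sample = ids, level = sample(c("high", "low"), 400, TRUE))
  tab <- table(combine_markers(s1, s2)$label)
  expect_identical(length(tab), 4L)
  expect_true(all(abs(tab - 100) <= 30))
})

test_that("group hazard ratios are reference-consistent", {
  surv <- simulate_survival(rep(c(0, log(2.5)), each = 150),
                            baseline_rate = 0.02, censor_rate = 0.005,
                            admin_cutoff = 200, rng_seed = 77)
  st <- data.frame(sample = surv$sample,
                   level = rep(c("lo", "hi"), each = 150))
  hr_lo <- cox_hr_groups(surv, st, reference = "lo")
  hr_hi <- cox_hr_groups(surv, st, reference = "hi")
  expect_equal(hr_lo$hr[hr_lo$label == "hi"],
               1 / hr_hi$hr[hr_hi$label == "lo"], tolerance = 1e-10)
  expect_true(hr_lo$ci_lo < hr_lo$hr & hr_lo$hr < hr_lo$ci_hi)

  # identical groups: HR ~ 1 inside its CI
  surv_id <- survival_table(data.frame(sample = paste0("s", 1:40),
                                       time = rep(rexp(20, 0.1) + 0.1, 2),
                                       event = rep(rbinom(20, 1, 0.8), 2)))
  st_id <- data.frame(sample = paste0("s", 1:40),
                      level = rep(c("g1", "g2"), each = 20))
  hr_id <- cox_hr_groups(surv_id, st_id, reference = "g1")
  expect_true(hr_id$ci_lo <= 1 & 1 <= hr_id$ci_hi)

  # degenerate: reference without events
  surv_d <- survival_table(data.frame(sample = c("a", "b", "c", "d"),
                                      time = 1:4, event = c(0, 0, 1, 1)))
  st_d <- data.frame(sample = c("a", "b", "c", "d"),
                     level = c("ref", "ref", "oth", "oth"))
  expect_error(cox_hr_groups(surv_d, st_d, reference = "ref"), "no events")
})
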