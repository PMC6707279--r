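# Marker dichotomization (IHC score or expression), Kaplan-Meier curves,
# log-rank testing, and single / combined two-marker hazard ratios.

#' Dichotomize IHC scores into low / high marker status
#'
#' Staining scores 0-1 are `low`, scores 2-3 are `high`.
#'
#' @param ihc validated IHC table ([ihc_table()]).
#' @param marker marker name; samples lacking the marker are simply absent
#'   from the output.
#' @return data frame of class `marker_status`: `sample`, `marker`,
#'   `level` (`"low"`/`"high"`), with the dichotomization rule in the
#'   `rule` attribute.
#' @export
dichotomize_ihc <- function(ihc, marker) {
  ihc <- ihc_table(ihc)
  marker <- toupper(marker)
  sub <- ihc[ihc$marker == marker, , drop = FALSE]
  assert_that(nrow(sub) > 0L, "no IHC records for marker '", marker, "'")
  out <- data.frame(sample = sub$sample, marker = marker,
                    level = ifelse(sub$score >= 2L, "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "rule") <- "IHC score 0-1 = low, 2-3 = high"
  class(out) <- c("marker_status", "data.frame")
  out
}

#' Dichotomize an expression vector into low / high marker status
#'
#' Splits per-sample expression at a threshold: the cohort median
#' (default), a quantile, or a fixed value.  Ties at the threshold go to
#' `low` (level is `high` iff value > threshold).
#'
#' @param values named numeric vector (names = sample ids).
#' @param marker marker name recorded in the output.
#' @param rule `"median"`, `"quantile"` or `"value"`.
#' @param q quantile in (0, 1) when `rule = "quantile"`.
#' @param value threshold when `rule = "value"`.
#' @return `marker_status` data frame as in [dichotomize_ihc()]; warns when
#'   every value is identical (all samples `low`).
#' @export
dichotomize_expression <- function(values, marker = "marker",
                                   rule = c("median", "quantile", "value"),
                                   q = 0.5, value = NULL) {
  rule <- match.arg(rule)
  assert_that(!is.null(names(values)), "values must be named by sample")
  assert_that(all(is.finite(values)), "values must be finite")
  thr <- switch(rule,
                median = stats::median(values),
                quantile = {
                  assert_that(q > 0 && q < 1, "q must lie in (0, 1)")
                  stats::quantile(values, q, names = FALSE)
                },
                value = {
                  assert_that(is.numeric(value) && length(value) == 1L,
                              "rule = 'value' needs a numeric threshold")
                  value
                })
  if (stats::sd(values) == 0)
    warning("all expression values identical; every sample classified low",
            call. = FALSE)
  out <- data.frame(sample = names(values), marker = toupper(marker),
                    level = ifelse(values > thr, "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "rule") <- sprintf("expression > %.6g = high (%s split, ties low)",
                               thr, rule)
  class(out) <- c("marker_status", "data.frame")
  out
}

# align survival with a per-sample grouping vector (named by sample)
.surv_groups <- function(surv, status) {
  surv <- survival_table(surv)
  assert_that(all(c("sample", "level") %in% names(status)) ||
                all(c("sample", "label") %in% names(status)),
              "status needs columns sample and level/label")
  grp <- if ("level" %in% names(status)) status$level else status$label
  names(grp) <- status$sample
  common <- intersect(surv$sample, names(grp))
  n_drop <- (nrow(surv) - length(common)) + (length(grp) - length(common))
  if (n_drop > 0)
    message(sprintf("dropped %d sample(s) without both survival and marker status",
                    n_drop))
  assert_that(length(common) >= 2L, "fewer than 2 samples with survival and status")
  i <- match(common, surv$sample)
  data.frame(sample = common, time = surv$time[i], event = surv$event[i],
             group = unname(grp[common]), stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival curves per marker group
#'
#' Product-limit estimate per group; groups without any event are skipped
#' with a warning (their curve would never drop).
#'
#' @param surv survival table.
#' @param status `marker_status` (or any data frame with `sample` and
#'   `level`/`label`).
#' @return list of class `km_result`: `fit` (the `survfit` object) and
#'   `table` (tidy per-group step function: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`).
#' @export
km_estimate <- function(surv, status) {
  d <- .surv_groups(surv, status)
  ev <- tapply(d$event, d$group, sum)
  dead_groups <- names(ev)[ev == 0]
  if (length(dead_groups)) {
    warning("group(s) without events skipped: ",
            paste(dead_groups, collapse = ", "), call. = FALSE)
    d <- d[!(d$group %in% dead_groups), , drop = FALSE]
  }
  assert_that(nrow(d) > 0L, "no group with at least one event")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(d$group), length(s$time))
         else sub("^group=", "", as.character(s$strata))
  tab <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, surv = s$surv,
                    stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab), class = "km_result")
}

#' Log-rank test across marker groups
#'
#' Standard log-rank chi-square with (k - 1) degrees of freedom across k
#' groups.
#'
#' @inheritParams km_estimate
#' @return list: `chi2`, `df`, `p`, `n`, `n_events`.
#' @export
logrank_test <- function(surv, status) {
  d <- .surv_groups(surv, status)
  groups <- unique(d$group)
  assert_that(length(groups) >= 2L, "log-rank needs >= 2 groups")
  assert_that(all(table(d$group) >= 1L), "empty group")
  assert_that(sum(d$event) >= 2L, "log-rank needs >= 2 events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1L
  list(chi2 = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       n = nrow(d), n_events = sum(d$event))
}

#' Combine two dichotomized markers into a four-level label
#'
#' Samples classified for both markers get the cross-product label
#' `"a-<level>/b-<level>"` (`a` = first argument, `b` = second); samples
#' missing either marker are dropped with a message.
#'
#' @param status_a,status_b `marker_status` data frames.
#' @return data frame: `sample`, `label`.
#' @export
combine_markers <- function(status_a, status_b) {
  for (s in list(status_a, status_b))
    assert_that(all(c("sample", "level") %in% names(s)),
                "inputs must be marker_status data frames")
  m <- merge(status_a[, c("sample", "level")],
             status_b[, c("sample", "level")],
             by = "sample", suffixes = c("_a", "_b"))
  n_drop <- nrow(status_a) + nrow(status_b) - 2L * nrow(m)
  if (n_drop > 0)
    message(sprintf("dropped %d record(s) lacking one of the two markers",
                    n_drop))
  data.frame(sample = m$sample,
             label = sprintf("a-%s/b-%s", m$level_a, m$level_b),
             stringsAsFactors = FALSE)
}

#' Hazard ratios of marker groups against a reference group
#'
#' Cox proportional-hazards fit on group indicator contrasts; one hazard
#' ratio (with Wald 95% CI and p) per non-reference label.  For the
#' combined two-marker analysis the conventional reference is the
#' doubly-protective cell, e.g. `"a-low/b-high"` when marker a is adverse
#' and marker b protective.
#'
#' @param surv survival table.
#' @param labels data frame (`sample`, `label`) as from
#'   [combine_markers()], or any `marker_status`.
#' @param reference reference label; must be present with >= 1 event.
#' @return data frame: `label`, `n`, `n_events`, `hr`, `ci_lo`, `ci_hi`,
#'   `p_wald`.
#' @export
cox_hr_groups <- function(surv, labels, reference) {
  d <- .surv_groups(surv, labels)
  present <- unique(d$group)
  assert_that(reference %in% present, "reference label '", reference,
              "' not present")
  assert_that(sum(d$event[d$group == reference]) >= 1L,
              "reference group has no events")
  assert_that(sum(d$event) >= 2L, "need >= 2 events")
  assert_that(length(present) >= 2L, "need >= 2 groups")
  d$group <- stats::relevel(factor(d$group), ref = reference)
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = d,
                         ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  lab <- sub("^group", "", names(beta))
  n <- table(d$group)[lab]
  ev <- tapply(d$event, d$group, sum)[lab]
  out <- data.frame(label = lab, n = as.integer(n),
                    n_events = as.integer(ev),
                    hr = exp(unname(beta)),
                    ci_lo = exp(unname(beta - 1.96 * se)),
                    ci_hi = exp(unname(beta + 1.96 * se)),
                    p_wald = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  rownames(out) <- NULL
  out
}
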