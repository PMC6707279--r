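# Pre-ranked gene-set enrichment (weighted Kolmogorov-Smirnov running
# sum), hypergeometric over-representation, and the signed-network
# upstream-regulator activation z-score.

# Enrichment score from sorted hit positions without building the full
# running sum: extrema of the running sum can only occur immediately after
# a hit (local maxima) or immediately before one (local minima), plus the
# zero start.  `a` is |score|^p over the whole ranked list.
.es_from_positions <- function(pos, a, N) {
  k <- length(pos)
  if (k == N) return(1)            # no misses: the sum climbs straight to 1
  w <- a[pos]
  if (sum(w) == 0) w <- rep(1, k)  # all-zero hit scores: equal weights
  cw <- cumsum(w)
  cw <- cw / cw[k]                 # normalized so the last hit lands at 1 exactly
  w <- diff(c(0, cw))
  d <- 1 / (N - k)
  after <- cw - (pos - seq_len(k)) * d
  before <- after - w
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Weighted-KS running-sum enrichment score
#'
#' Walks a ranked gene list: members of the set increment the running sum
#' by `|score|^weight_p` (normalized over the hits), non-members decrement
#' it by `1/(N - N_hits)`.  The enrichment score (ES) is the signed maximum
#' deviation from zero.  A set occupying the top of the list scores
#' exactly +1.
#'
#' @param ranked data frame (`gene`, `score`) ordered by descending score;
#'   genes must be unique.
#' @param gene_set character vector of member symbols; at least one must be
#'   present in the ranked list.
#' @param weight_p score weighting exponent; 1 (default) is the weighted
#'   statistic, 0 the classic Kolmogorov-Smirnov variant.
#' @return list: `es`, `running` (full running-sum profile), `n_hits`,
#'   `leading_edge` (members at or before the extremum for positive ES, at
#'   or after it for negative ES).
#' @export
es_running_sum <- function(ranked, gene_set, weight_p = 1) {
  assert_that(all(c("gene", "score") %in% names(ranked)),
              "ranked must have columns gene, score")
  assert_that(!anyDuplicated(ranked$gene), "ranked genes must be unique")
  assert_that(weight_p >= 0, "weight_p must be >= 0")
  gene_set <- toupper(gene_set)
  N <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  k <- sum(hit)
  assert_that(k >= 1L, "no gene-set member present in the ranked list")
  a <- abs(ranked$score)^weight_p
  if (k == N) {
    w <- if (sum(a) > 0) a else rep(1, N)
    running <- cumsum(w) / sum(w)
    running[N] <- 1
    return(list(es = 1, running = running, n_hits = k,
                leading_edge = ranked$gene))
  }
  w_hit <- a[hit]
  if (sum(w_hit) == 0) w_hit <- rep(1, k)
  cw <- cumsum(w_hit)
  cw <- cw / cw[k]               # last hit lands at 1 exactly
  # running sum at position i: normalized hit mass so far minus the miss
  # penalty accumulated so far
  running <- c(0, cw)[cumsum(hit) + 1L] - cumsum(!hit) / (N - k)
  hi <- max(running, 0); lo <- min(running, 0)
  es <- if (hi >= -lo) hi else lo
  le <- if (es > 0) {
    i_max <- which(running == hi)[1L]
    ranked$gene[hit & seq_len(N) <= i_max]
  } else if (es < 0) {
    i_min <- which(running == lo)[1L]
    ranked$gene[hit & seq_len(N) >= i_min]
  } else character()
  list(es = es, running = running, n_hits = k, leading_edge = le)
}

#' Pre-ranked gene-set enrichment analysis with permutation p-values
#'
#' For each collection set, computes the weighted-KS enrichment score on
#' the ranked list, then a gene-label permutation null: `n_perm` random
#' same-size draws from the ranked universe.  The permutation p-value is
#' the one-sided tail among same-sign null scores with a continuity
#' correction; NES is the ES divided by the mean |null ES| of the same
#' sign; FDR is Benjamini-Hochberg across the reported sets.  Sets with no
#' member in the universe, or larger than the universe, are skipped with a
#' warning.
#'
#' @param ranked data frame (`gene`, `score`), descending score order.
#' @param collection named list of member vectors ([read_gmt()]).
#' @param weight_p score weighting exponent (default 1).
#' @param n_perm number of permutations, >= 100.
#' @param rng_seed integer seed for reproducible permutations.
#' @return data frame: `set`, `es`, `nes`, `p_perm`, `fdr`, `n_hits`,
#'   `leading_edge` (comma-separated).
#' @export
preranked_gsea <- function(ranked, collection, weight_p = 1, n_perm = 1000L,
                           rng_seed = NULL) {
  assert_that(n_perm >= 100L, "n_perm must be >= 100")
  assert_that(length(collection) >= 1L, "empty gene-set collection")
  assert_that(all(c("gene", "score") %in% names(ranked)),
              "ranked must have columns gene, score")
  N <- nrow(ranked)
  a <- abs(ranked$score)^weight_p
  with_seed(rng_seed, {
    rows <- lapply(names(collection), function(nm) {
      members <- toupper(collection[[nm]])
      if (length(members) > N) {
        warning("set '", nm, "' larger than the ranked universe; skipped",
                call. = FALSE)
        return(NULL)
      }
      obs <- tryCatch(es_running_sum(ranked, members, weight_p),
                      error = function(e) NULL)
      if (is.null(obs)) {
        warning("set '", nm, "' has no member in the ranked list; skipped",
                call. = FALSE)
        return(NULL)
      }
      k <- obs$n_hits
      null_es <- vapply(seq_len(n_perm), function(i) {
        .es_from_positions(sort(sample.int(N, k)), a, N)
      }, 0)
      same <- if (obs$es >= 0) null_es[null_es > 0] else null_es[null_es < 0]
      if (length(same) == 0L) {
        p <- 1 / (n_perm + 1)
        nes <- NA_real_
      } else {
        p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
        nes <- obs$es / mean(abs(same))
      }
      data.frame(set = nm, es = obs$es, nes = nes, p_perm = p,
                 n_hits = k,
                 leading_edge = paste(obs$leading_edge, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    rows <- Filter(Negate(is.null), rows)
    assert_that(length(rows) > 0L, "no set had members in the ranked list")
    out <- do.call(rbind, rows)
    out$fdr <- stats::p.adjust(out$p_perm, method = "BH")
    out <- out[, c("set", "es", "nes", "p_perm", "fdr", "n_hits",
                   "leading_edge")]
    rownames(out) <- NULL
    out
  })
}

#' Hypergeometric over-representation analysis
#'
#' One-sided over-representation of a query gene set in each collection
#' set, against a stated universe: `p = P(X >= k)` for hypergeometric X
#' with the set's universe overlap as successes and the query size as
#' draws.  Benjamini-Hochberg adjustment across sets.  This is the generic
#' Fisher-style pathway over-representation test, a declared stand-in for
#' proprietary pathway-scoring tools.
#'
#' @param query character vector of gene symbols; members outside the
#'   universe are dropped with a message, and an empty usable query is an
#'   error.
#' @param collection named list of member vectors.
#' @param universe character vector of all assayable gene symbols.
#' @return data frame: `set`, `n_set` (universe overlap of the set),
#'   `n_overlap` (with the query), `p`, `p_bh`, `neg_log10_p`.
#' @export
overrepresentation <- function(query, collection, universe) {
  assert_that(length(universe) >= 1L, "empty universe")
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside))
    message(sprintf("dropped %d query gene(s) outside the universe",
                    length(outside)))
  query <- intersect(query, universe)
  assert_that(length(query) >= 1L, "no query gene lies in the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set_u <- intersect(unique(toupper(collection[[nm]])), universe)
    K <- length(set_u)
    if (K == 0L) return(NULL)
    k <- length(intersect(set_u, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  assert_that(length(rows) > 0L, "no collection set overlaps the universe")
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$neg_log10_p <- -log10(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upstream-regulator activation z-score over a signed target network
#'
#' For each regulator, compares the observed direction of its targets with
#' the sign of the regulator-to-target edges: a target is consistent when
#' `edge_sign * observed_direction = +1`.  The activation z is
#' `(N_consistent - N_inconsistent) / sqrt(N)` over the regulator's
#' observed targets; z >= 2 calls the regulator `activated`, z <= -2
#' `inhibited`, otherwise `not-significant`.  Regulators with fewer than 3
#' observed targets are reported but flagged low-evidence.
#'
#' @param network data frame with columns `regulator`, `target`, `sign`
#'   (+1 activating edge, -1 repressing edge).
#' @param observed data frame with columns `gene`, `direction` (+1 the
#'   gene is up/adverse in the signature, -1 down/protective).
#' @return data frame: `regulator`, `n_targets_observed`, `z_activation`,
#'   `state`, `low_evidence`.
#' @export
upstream_activation_z <- function(network, observed) {
  assert_that(all(c("regulator", "target", "sign") %in% names(network)),
              "network needs columns regulator, target, sign")
  assert_that(all(c("gene", "direction") %in% names(observed)),
              "observed needs columns gene, direction")
  assert_that(all(network$sign %in% c(-1, 1)),
              "edge signs must be +1 or -1")
  assert_that(all(observed$direction %in% c(-1, 1)),
              "observed directions must be +1 or -1")
  net <- data.frame(regulator = toupper(network$regulator),
                    target = toupper(network$target),
                    sign = network$sign, stringsAsFactors = FALSE)
  obs <- data.frame(gene = toupper(observed$gene),
                    direction = observed$direction,
                    stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(obs$gene), "duplicate genes in observed")
  m <- merge(net, obs, by.x = "target", by.y = "gene")
  assert_that(nrow(m) > 0L, "no network target was observed")
  consistent <- m$sign * m$direction == 1
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(m)), nc = as.integer(consistent)),
                          by = list(regulator = m$regulator), FUN = sum)
  z <- (agg$nc - (agg$n - agg$nc)) / sqrt(agg$n)
  state <- ifelse(z >= 2, "activated",
                  ifelse(z <= -2, "inhibited", "not-significant"))
  out <- data.frame(regulator = agg$regulator,
                    n_targets_observed = agg$n,
                    z_activation = z, state = state,
                    low_evidence = agg$n < 3L, stringsAsFactors = FALSE)
  out <- out[order(-out$z_activation, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked list of a consensus signature for enrichment
#'
#' Converts a consensus signature into the (gene, score) ranking fed to
#' [preranked_gsea()], using the per-gene survival z as the score (sign
#' encodes adverse vs protective).
#'
#' @param consensus a `consensus_signature`.
#' @return data frame (`gene`, `score`) in descending score order.
#' @export
consensus_ranking <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_signature"))
  g <- consensus$genes
  out <- data.frame(gene = g$gene, score = g$z, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
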