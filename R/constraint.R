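#' Observed mean minimum phylogenetic distance for one presence
#'
#' For one (OTU, fragment) presence: each non-preferred host that harbors the
#' OTU in the fragment is matched to its closest relative among the OTU's
#' preferred hosts, and the resulting minimum cophenetic distances are
#' averaged.
#'
#' @param nonpref_observed character vector of non-preferred species that
#'   harbor the OTU in the fragment (length k >= 1).
#' @param preferred character vector of the OTU's preferred hosts (>= 1).
#' @param dist cophenetic distance matrix (species x species).
#' @return Mean over the k hosts of the minimum distance to a preferred host.
#' @export
observed_statistic <- function(nonpref_observed, preferred, dist) {
  stopifnot(length(nonpref_observed) >= 1, length(preferred) >= 1)
  missing <- setdiff(c(nonpref_observed, preferred), rownames(dist))
  if (length(missing) > 0) {
    stop("species absent from distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- dist[nonpref_observed, preferred, drop = FALSE]
  mean(apply(sub, 1, min))
}

#' Null expectation of the minimum-distance statistic for one presence
#'
#' Draws `n_iter` random sets of k species (k = number of observed
#' non-preferred hosts) uniformly without replacement from the candidate pool
#' -- the species present in the fragment minus the OTU's preferred hosts --
#' and returns the mean of the statistic over draws.
#'
#' @param k number of species per draw.
#' @param pool candidate species (present in the fragment, not preferred).
#' @param preferred the OTU's preferred hosts.
#' @param dist cophenetic distance matrix.
#' @param n_iter number of random draws (default 999); `n_iter = 1`
#'   reproduces a single-draw null.
#' @return Mean of the statistic over the draws; `NA` if the pool is smaller
#'   than k (the presence cannot be randomized).
#' @export
null_statistic <- function(k, pool, preferred, dist, n_iter = 999) {
  if (length(pool) < k) return(NA_real_)
  # min distance to the preferred set, per pool species, computed once
  md <- apply(dist[pool, preferred, drop = FALSE], 1, min)
  if (length(pool) == k) return(mean(md))  # only one possible draw
  draws <- vapply(seq_len(n_iter),
                  function(i) mean(md[sample.int(length(md), k)]),
                  numeric(1))
  mean(draws)
}

# Paired test on observed - expected differences: one-sample two-sided
# t-test against 0 (t.test), plus degenerate-input guards.
paired_diff_test <- function(d) {
  if (length(d) < 2) stop("need at least 2 differences for the t-test",
                          call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("zero variance of observed - expected differences; test undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(d, mu = 0, alternative = "two.sided")
  list(n = length(d), estimate = unname(ht$estimate),
       t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Test for phylogenetically constrained rewiring
#'
#' For every eligible (OTU, fragment) presence, computes the observed mean
#' minimum cophenetic distance from the non-preferred hosts harboring the OTU
#' to their closest preferred host, and the null expectation obtained by
#' drawing the same number of species at random from the plants present in
#' the fragment (preferred hosts excluded). The per-presence differences
#' observed - expected are then tested against zero with a two-sided paired
#' t-test: a significantly negative estimate means rewired interactions fall
#' closer to preferred hosts on the phylogeny than chance predicts.
#'
#' @param dataset a `community_dataset`.
#' @param prefs a `preference_table`; computed from `dataset` if missing.
#' @param n_iter random draws per presence for the null expectation
#'   (default 999; use 1 for a single-draw null).
#' @param in_fragment_preferred if `TRUE`, the reference preferred set is
#'   restricted to preferred hosts present in the focal fragment (default
#'   `FALSE`: the OTU's global preferred set).
#' @param seed optional integer seed for the null draws.
#' @return A `constraint_test` object: list with `n`, `estimate`, `t`, `df`,
#'   `p`, `n_dropped` (presences whose candidate pool was smaller than k),
#'   `n_iter`, and `stats`, the per-presence table (`otu_id`, `fragment_id`,
#'   `k`, `observed`, `expected`, `diff`).
#' @export
constraint_test <- function(dataset, prefs = NULL, n_iter = 999,
                            in_fragment_preferred = FALSE, seed = NULL) {
  stopifnot(inherits(dataset, "community_dataset"))
  if (is.null(prefs)) prefs <- classify_hosts(cooccurrence_counts(dataset))
  if (!is.null(seed)) set.seed(seed)
  pres <- eligible_presences(dataset, prefs)
  if (nrow(pres) == 0) stop("no eligible presences", call. = FALSE)
  nets <- species_networks(dataset)
  pref_by_otu <- split_hosts(prefs, "preferred")
  dist <- dataset$phylo_dist

  obs <- exp_ <- numeric(nrow(pres))
  kk <- integer(nrow(pres))
  keep <- logical(nrow(pres))
  for (i in seq_len(nrow(pres))) {
    o <- pres$otu_id[i]
    f <- pres$fragment_id[i]
    np <- pres$nonpreferred_observed[[i]]
    preferred <- pref_by_otu[[o]]
    present <- colnames(nets[[f]])
    if (in_fragment_preferred) {
      pf <- intersect(preferred, present)
      if (length(pf) > 0) preferred <- pf
    }
    pool <- setdiff(present, pref_by_otu[[o]])
    kk[i] <- length(np)
    obs[i] <- observed_statistic(np, preferred, dist)
    exp_[i] <- null_statistic(kk[i], pool, preferred, dist, n_iter)
    keep[i] <- !is.na(exp_[i])
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " presence(s) dropped: candidate pool smaller than k")
  }
  stats_tab <- data.frame(otu_id = pres$otu_id, fragment_id = pres$fragment_id,
                          k = kk, observed = obs, expected = exp_,
                          diff = obs - exp_)[keep, , drop = FALSE]
  rownames(stats_tab) <- NULL
  res <- paired_diff_test(stats_tab$diff)
  structure(c(res, list(n_dropped = n_dropped, n_iter = n_iter,
                        stats = stats_tab)),
            class = "constraint_test")
}

#' @export
print.constraint_test <- function(x, ...) {
  cat("Phylogenetic constraint on rewired interactions\n")
  cat("  paired t-test on observed - expected minimum distances\n")
  cat(sprintf("  n = %d presences (%d dropped), null draws per presence = %d\n",
              x$n, x$n_dropped, x$n_iter))
  cat(sprintf("  estimate = %.4g, t = %.4g, df = %d, p = %.4g\n",
              x$estimate, x$t, x$df, x$p))
  invisible(x)
}
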