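#' Interaction set of a species-level network
#'
#' One (species, OTU) pair per 1-cell of the species-level incidence matrix,
#' encoded as `"species||otu"` strings so standard set operations apply.
#'
#' @param net binary OTU x species matrix (see [aggregate_to_species()]).
#' @return Character vector of unique interaction keys (possibly empty).
#' @export
interaction_set <- function(net) {
  idx <- which(net == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  sort(paste(colnames(net)[idx[, 2]], rownames(net)[idx[, 1]], sep = "||"))
}

#' Dissimilarity between two interaction sets
#'
#' Whittaker's multiplicative form `S / alpha-bar - 1` with `S` the size of
#' the union and `alpha-bar` the mean set size, or the Sorensen form
#' `(b + c) / (2a + b + c)`. Both lie in `[0, 1]`, are 0 iff the sets are
#' equal and 1 iff they are disjoint.
#'
#' @param a,b character vectors of interaction keys.
#' @param metric `"whittaker"` (default) or `"sorensen"`.
#' @return A number in `[0, 1]`, or `NA` if both sets are empty.
#' @export
set_dissimilarity <- function(a, b, metric = c("whittaker", "sorensen")) {
  metric <- match.arg(metric)
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  shared <- length(intersect(a, b))
  if (metric == "whittaker") {
    S <- length(a) + length(b) - shared
    abar <- (length(a) + length(b)) / 2
    S / abar - 1
  } else {
    bb <- length(a) - shared
    cc <- length(b) - shared
    (bb + cc) / (2 * shared + bb + cc)
  }
}

#' Partition the dissimilarity of two fragment networks
#'
#' Decomposes the overall interaction dissimilarity between two fragments
#' (`beta_wn`) into a rewiring component measured on the subnetworks shared
#' by both fragments (`beta_os`) and a species-turnover component
#' (`beta_st = beta_wn - beta_os`). The ratio `beta_st / beta_wn` is the
#' contribution of species turnover; its complement `1 - beta_st / beta_wn`
#' is used downstream as a rewiring probability.
#'
#' The shared subnetwork is induced, by default, by the plant species present
#' in both fragments AND the OTUs present in both fragments
#' (`shared = "both"`); `shared = "plants"` restricts on plant species only.
#' If there is no shared species (or no shared OTU under `"both"`), `beta_os`
#' and the downstream fields are `NA`.
#'
#' @param net_a,net_b binary OTU x species matrices of the two fragments.
#' @param metric dissimilarity metric, see [set_dissimilarity()].
#' @param shared which nodes induce the shared subnetwork.
#' @return One-row data.frame: `beta_wn`, `beta_os`, `beta_st`, `ratio_st_wn`.
#' @export
partition_pair <- function(net_a, net_b, metric = c("whittaker", "sorensen"),
                           shared = c("both", "plants")) {
  metric <- match.arg(metric)
  shared <- match.arg(shared)
  set_a <- interaction_set(net_a)
  set_b <- interaction_set(net_b)
  beta_wn <- set_dissimilarity(set_a, set_b, metric)

  sp <- intersect(colnames(net_a), colnames(net_b))
  ot <- intersect(rownames(net_a), rownames(net_b))
  no_shared <- length(sp) == 0 || (shared == "both" && length(ot) == 0)
  if (no_shared) {
    beta_os <- NA_real_
  } else {
    if (shared == "both") {
      sub_a <- net_a[rownames(net_a) %in% ot, sp, drop = FALSE]
      sub_b <- net_b[rownames(net_b) %in% ot, sp, drop = FALSE]
    } else {
      sub_a <- net_a[, sp, drop = FALSE]
      sub_b <- net_b[, sp, drop = FALSE]
    }
    beta_os <- set_dissimilarity(interaction_set(sub_a), interaction_set(sub_b),
                                 metric)
    if (is.na(beta_os) && !is.na(beta_wn)) beta_os <- 0  # shared subnets both empty
  }
  beta_st <- if (is.na(beta_wn) || is.na(beta_os)) NA_real_ else beta_wn - beta_os
  ratio <- if (is.na(beta_st) || is.na(beta_wn) || beta_wn == 0) NA_real_ else
    beta_st / beta_wn
  data.frame(beta_wn = beta_wn, beta_os = beta_os, beta_st = beta_st,
             ratio_st_wn = ratio)
}

#' Beta-diversity partition over all fragment pairs
#'
#' Applies [partition_pair()] to every unordered pair of fragments
#' (`n * (n - 1) / 2` rows) and summarises the turnover ratio.
#'
#' @param dataset a `community_dataset`.
#' @inheritParams partition_pair
#' @return A `beta_partition` data.frame with columns `fragment_a`,
#'   `fragment_b`, `beta_wn`, `beta_os`, `beta_st`, `ratio_st_wn`, carrying
#'   attributes `mean_ratio` and `se_ratio` (over rows with a defined ratio).
#' @export
partition_all <- function(dataset, metric = c("whittaker", "sorensen"),
                          shared = c("both", "plants")) {
  stopifnot(inherits(dataset, "community_dataset"))
  metric <- match.arg(metric)
  shared <- match.arg(shared)
  nets <- species_networks(dataset)
  frag <- names(nets)
  if (length(frag) < 2) stop("need at least 2 fragments", call. = FALSE)
  pairs <- utils::combn(frag, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    cbind(data.frame(fragment_a = a, fragment_b = b),
          partition_pair(nets[[a]], nets[[b]], metric, shared))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  r <- out$ratio_st_wn[!is.na(out$ratio_st_wn)]
  attr(out, "mean_ratio") <- if (length(r) > 0) mean(r) else NA_real_
  attr(out, "se_ratio") <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
  attr(out, "metric") <- metric
  class(out) <- c("beta_partition", "data.frame")
  out
}

#' @export
print.beta_partition <- function(x, ...) {
  cat("Interaction beta-diversity partition (", attr(x, "metric"),
      " dissimilarity)\n", sep = "")
  cat("  fragment pairs: ", nrow(x), " (", sum(!is.na(x$ratio_st_wn)),
      " with defined turnover ratio)\n", sep = "")
  cat(sprintf("  mean beta_ST/beta_WN: %.3f +/- %.3f (SE)\n",
              attr(x, "mean_ratio"), attr(x, "se_ratio")))
  NextMethod()
}

# Pool of per-step rewiring probabilities 1 - beta_ST/beta_WN (defined rows).
rewire_probability_pool <- function(beta) {
  r <- beta$ratio_st_wn
  1 - r[!is.na(r)]
}
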