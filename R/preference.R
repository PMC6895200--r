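#' Co-occurrence opportunities and realizations per (OTU, plant species) pair
#'
#' For every fungal OTU and plant species, counts across fragments how often
#' the two co-occur (the OTU detected in at least one individual of the
#' fragment, the species with at least one sampled individual there) -- the
#' number of potential interactions -- and in how many of those fragments the
#' species-level interaction is actually observed.
#'
#' @param dataset a `community_dataset`.
#' @return data.frame `otu_id`, `species`, `n_potential`, `n_realized`, one
#'   row per pair with `n_potential >= 1`.
#' @export
cooccurrence_counts <- function(dataset) {
  stopifnot(inherits(dataset, "community_dataset"))
  nets <- species_networks(dataset)
  otus <- sort(unique(unlist(lapply(nets, rownames))))
  species <- dataset$taxonomy$species
  n_pot <- matrix(0L, length(otus), length(species),
                  dimnames = list(otus, species))
  n_real <- n_pot
  for (net in nets) {
    o <- rownames(net)         # OTUs present in the fragment
    s <- colnames(net)         # species present in the fragment
    n_pot[o, s] <- n_pot[o, s] + 1L
    n_real[o, s] <- n_real[o, s] + net
  }
  idx <- which(n_pot > 0, arr.ind = TRUE)
  out <- data.frame(otu_id = otus[idx[, 1]], species = species[idx[, 2]],
                    n_potential = n_pot[idx], n_realized = n_real[idx],
                    stringsAsFactors = FALSE)
  out[order(out$otu_id, out$species), , drop = FALSE]
}

#' Classify hosts as preferred, non-preferred or undetermined
#'
#' A plant species is a *preferred* host of an OTU when it harbored the OTU
#' in strictly more than `threshold` of their potential interactions and the
#' pair co-occurred in at least `min_potential` fragments (the support rule
#' guards against extreme percentages from few co-occurrences). Species that
#' harbored the OTU at least once but are not preferred are *non-preferred*
#' (flagged `low_support` when below `min_potential`); co-occurring species
#' that never harbored the OTU are *undetermined*. By default
#' (`strict = TRUE`) harboring pairs below `min_potential` are `excluded`
#' from both host sets: with few co-occurrences the realization fraction is
#' too noisy to call a host either preferred or non-preferred, and treating
#' such hosts as non-preferred leaks genuinely preferred hosts (whose
#' relatives are close by construction) into the rewired-host set, biasing
#' the downstream null-model test. `strict = FALSE` instead labels them
#' non-preferred with the `low_support` flag.
#'
#' @param counts output of [cooccurrence_counts()].
#' @param min_potential minimum number of co-occurrences to support preferred
#'   status (default 4).
#' @param threshold realization fraction that must be exceeded (strictly) for
#'   preferred status (default 0.5, i.e. "more than half of the times").
#' @param strict exclude low-support harboring pairs from both host sets
#'   (default TRUE).
#' @return A `preference_table`: data.frame `otu_id`, `species`,
#'   `n_potential`, `n_realized`, `ratio`, `class` (one of `preferred`,
#'   `nonpreferred`, `undetermined`, `excluded`), `low_support`.
#' @export
classify_hosts <- function(counts, min_potential = 4, threshold = 0.5,
                           strict = TRUE) {
  ratio <- counts$n_realized / counts$n_potential
  preferred <- counts$n_potential >= min_potential & ratio > threshold
  harbors <- counts$n_realized >= 1
  low_support <- harbors & !preferred & counts$n_potential < min_potential
  cls <- ifelse(preferred, "preferred",
                ifelse(harbors, "nonpreferred", "undetermined"))
  if (strict) cls[low_support] <- "excluded"
  out <- cbind(counts,
               data.frame(ratio = ratio, class = cls,
                          low_support = low_support))
  rownames(out) <- NULL
  class(out) <- c("preference_table", "data.frame")
  out
}

#' @export
print.preference_table <- function(x, ...) {
  cat("Host-preference table:", length(unique(x$otu_id)), "OTUs,",
      nrow(x), "OTU-species pairs\n")
  print(table(x$class))
  invisible(x)
}

# Species sets per OTU by class; returns a character vector.
hosts_of_class <- function(prefs, otu, cls) {
  prefs$species[prefs$otu_id == otu & prefs$class == cls]
}

# Named list otu_id -> species vector for one class (drops empty OTUs).
split_hosts <- function(prefs, cls) {
  sub <- prefs[prefs$class == cls, , drop = FALSE]
  split(sub$species, sub$otu_id)
}

#' Preferred hosts of one OTU
#' @param prefs a `preference_table`.
#' @param otu OTU id.
#' @return Character vector of species names.
#' @export
preferred_hosts <- function(prefs, otu) hosts_of_class(prefs, otu, "preferred")

#' Non-preferred (harboring) hosts of one OTU
#' @inheritParams preferred_hosts
#' @return Character vector of species names.
#' @export
nonpreferred_hosts <- function(prefs, otu) hosts_of_class(prefs, otu, "nonpreferred")

#' Per-fragment OTU presences eligible for the constraint test
#'
#' An (OTU, fragment) presence enters the phylogenetic-constraint analysis
#' when the OTU is detected in the fragment, has at least one globally
#' preferred host, and at least one of its non-preferred hosts harbors it in
#' that fragment (i.e. the fragment shows a rewired interaction).
#'
#' @param dataset a `community_dataset`.
#' @param prefs a `preference_table` from [classify_hosts()].
#' @return data.frame `otu_id`, `fragment_id`, `nonpreferred_observed`
#'   (list-column of species character vectors).
#' @export
eligible_presences <- function(dataset, prefs) {
  stopifnot(inherits(dataset, "community_dataset"),
            inherits(prefs, "preference_table"))
  nets <- species_networks(dataset)
  pref_by_otu <- split_hosts(prefs, "preferred")
  nonpref_by_otu <- split_hosts(prefs, "nonpreferred")
  has_pref <- names(pref_by_otu)
  rows <- list()
  for (f in names(nets)) {
    net <- nets[[f]]
    for (o in intersect(rownames(net), has_pref)) {
      observed <- colnames(net)[net[o, ] == 1L]
      np <- intersect(observed, nonpref_by_otu[[o]])
      if (length(np) > 0) {
        rows[[length(rows) + 1L]] <-
          data.frame(otu_id = o, fragment_id = f,
                     nonpreferred_observed = I(list(sort(np))),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(otu_id = character(0), fragment_id = character(0),
                      nonpreferred_observed = I(list())))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
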