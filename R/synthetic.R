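#' Configuration for the synthetic community generator
#'
#' Defaults mirror the structure of the gypsum-outcrop study system the
#' pipeline targets: 15 habitat fragments, 15 sampled plant individuals per
#' fragment, 28 plant species in 13 families, 161 fungal OTUs.
#'
#' @param n_fragments number of habitat fragments.
#' @param n_individuals_per_fragment sampled plant individuals per fragment.
#' @param n_species number of plant species in the regional pool.
#' @param n_families number of plant families (each gets >= 1 species).
#' @param n_otus number of fungal OTUs.
#' @param species_occupancy probability that a species occurs in a fragment.
#' @param p_realize_preferred probability that a present preferred host
#'   harbors the OTU in a fragment.
#' @param p_rewire_gen probability that an OTU present in a fragment adds one
#'   rewired (non-preferred) host there.
#' @param p_individual probability that each individual of a harboring
#'   species carries the OTU (at least one always does).
#' @param tau phylogenetic kernel scale, in branch-length units, for choosing
#'   the rewired host: candidate weight is `exp(-d_min / tau)` with `d_min`
#'   the cophenetic distance to the nearest true preferred host. Small `tau`
#'   = strong constraint; `Inf` = uniform choice.
#' @param n_preferred_per_otu integer vector; each OTU's number of true
#'   preferred hosts is drawn uniformly from it.
#' @param tree_depth root age of the synthetic phylogeny (arbitrary units;
#'   think Myr).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_fragments = 15, n_individuals_per_fragment = 15,
                             n_species = 28, n_families = 13, n_otus = 161,
                             species_occupancy = 0.6,
                             p_realize_preferred = 0.9, p_rewire_gen = 0.25,
                             p_individual = 0.7, tau = 25,
                             n_preferred_per_otu = 1:3, tree_depth = 100) {
  cfg <- as.list(environment())
  probs <- c(cfg$species_occupancy, cfg$p_realize_preferred, cfg$p_rewire_gen,
             cfg$p_individual)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_families <= cfg$n_species,
            cfg$tau > 0, all(cfg$n_preferred_per_otu >= 1))
  structure(cfg, class = "synthetic_config")
}

# Random nested ultrametric clade from pre-built sub-clades.
# items: list of list(str=, age=); internal node ages drawn in
# (max(min_age, child ages), max_age), so branch lengths are positive.
join_clade <- function(items, max_age, min_age) {
  if (length(items) == 1) return(items[[1]])
  lo <- max(min_age, vapply(items, function(i) i$age, 0))
  age <- stats::runif(1, lo, max_age)
  ord <- sample(length(items))
  k <- if (length(items) == 2) 1 else sample(length(items) - 1, 1)
  left <- join_clade(items[ord[seq_len(k)]], age, min_age)
  right <- join_clade(items[ord[-seq_len(k)]], age, min_age)
  list(str = paste0("(", left$str, ":", sprintf("%.6f", age - left$age), ",",
                    right$str, ":", sprintf("%.6f", age - right$age), ")"),
       age = age)
}

#' Generate a family-structured ultrametric phylogeny and taxonomy
#'
#' Species are grouped into monophyletic family clades. Family crown nodes
#' are younger than 30% of the root age while all between-family divergences
#' are older than 55% of it, so every within-family cophenetic distance is
#' strictly smaller than every between-family distance -- the property the
#' rewiring kernel and the `RWphylo` scenario rely on.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `tree` (a `phylo`) and `taxonomy` (data.frame `species`,
#'   `family`).
#' @export
generate_phylogeny <- function(cfg) {
  ns <- cfg$n_species; nf <- cfg$n_families; depth <- cfg$tree_depth
  species <- sprintf("sp%02d", seq_len(ns))
  families <- sprintf("fam%02d", seq_len(nf))
  fam_of <- families[sample(c(seq_len(nf),
                              sample.int(nf, ns - nf, replace = TRUE)))]
  taxonomy <- data.frame(species = species, family = fam_of,
                         stringsAsFactors = FALSE)
  clades <- lapply(families, function(fm) {
    tips <- lapply(species[fam_of == fm], function(s) list(str = s, age = 0))
    join_clade(tips, max_age = 0.3 * depth, min_age = 0.01 * depth)
  })
  root <- join_clade(clades, max_age = depth, min_age = 0.55 * depth)
  tree <- ape::read.tree(text = paste0(root$str, ";"))
  list(tree = tree, taxonomy = taxonomy)
}

#' Generate fragment species pools and individual rosters
#'
#' Each species occurs in each fragment independently with probability
#' `species_occupancy`; each fragment's individuals are then sampled from its
#' occurring species with Dirichlet(1, ..., 1) relative abundances. Fragments
#' whose roster ends up with fewer than two species are redrawn (bounded).
#'
#' @param cfg a [synthetic_config()].
#' @param taxonomy data.frame `species`, `family`.
#' @return data.frame `individual_id`, `fragment_id`, `species`.
#' @export
generate_landscape <- function(cfg, taxonomy) {
  species <- taxonomy$species
  frag_ids <- sprintf("f%02d", seq_len(cfg$n_fragments))
  rosters <- lapply(frag_ids, function(f) {
    for (try in seq_len(200)) {
      present <- species[stats::runif(length(species)) < cfg$species_occupancy]
      if (length(present) < 2) next
      ab <- stats::rgamma(length(present), shape = 1)   # Dirichlet(1,...,1)
      roster <- sample(present, cfg$n_individuals_per_fragment,
                       replace = TRUE, prob = ab / sum(ab))
      if (length(unique(roster)) >= 2) {
        return(data.frame(
          individual_id = sprintf("%s_i%02d", f,
                                  seq_len(cfg$n_individuals_per_fragment)),
          fragment_id = f, species = roster, stringsAsFactors = FALSE))
      }
    }
    stop("could not draw a fragment with >= 2 species; species_occupancy too low",
         call. = FALSE)
  })
  do.call(rbind, rosters)
}

#' Generate interactions with known host preferences and rewiring
#'
#' Every OTU receives a true preferred host set (drawn with mild family
#' clustering: species in a family already represented in the set are three
#' times likelier to be added). In each fragment where at least one true
#' preferred host occurs, each present preferred host harbors the OTU with
#' `p_realize_preferred`; with probability `p_rewire_gen` the OTU additionally
#' rewires to one non-preferred present species chosen with weight
#' `exp(-d_min / tau)`. Harboring species pass the OTU to each of their
#' individuals with `p_individual` (at least one).
#'
#' @param cfg a [synthetic_config()].
#' @param individuals landscape roster from [generate_landscape()].
#' @param taxonomy data.frame `species`, `family`.
#' @param tree the `phylo` from [generate_phylogeny()].
#' @return List with `dataset` (a validated `community_dataset`) and `truth`
#'   (data.frame `otu_id`, `preferred` list-column, `tau`, `p_rewire_gen`).
#' @export
generate_interactions <- function(cfg, individuals, taxonomy, tree) {
  dist <- cophenetic_matrix(tree)[taxonomy$species, taxonomy$species]
  species <- taxonomy$species
  fam_of <- stats::setNames(taxonomy$family, taxonomy$species)
  frag_ids <- unique(individuals$fragment_id)
  present_by_frag <- lapply(split(individuals$species, individuals$fragment_id),
                            unique)[frag_ids]
  inds_by_frag_sp <- split(individuals$individual_id,
                           list(individuals$fragment_id, individuals$species),
                           drop = TRUE)

  otus <- sprintf("otu%03d", seq_len(cfg$n_otus))
  truth_pref <- vector("list", cfg$n_otus)
  cells <- vector("list", cfg$n_otus)

  for (oi in seq_along(otus)) {
    n_pref <- if (length(cfg$n_preferred_per_otu) == 1) cfg$n_preferred_per_otu
              else sample(cfg$n_preferred_per_otu, 1)
    pref <- sample(species, 1)
    while (length(pref) < n_pref) {
      cand <- setdiff(species, pref)
      w <- ifelse(fam_of[cand] %in% fam_of[pref], 3, 1)
      pref <- c(pref, sample(cand, 1, prob = w))
    }
    truth_pref[[oi]] <- sort(pref)
    d_min_all <- apply(dist[, pref, drop = FALSE], 1, min)

    for (f in frag_ids) {
      present <- present_by_frag[[f]]
      pres_pref <- intersect(pref, present)
      if (length(pres_pref) == 0) next
      realized <- pres_pref[stats::runif(length(pres_pref)) <
                              cfg$p_realize_preferred]
      if (stats::runif(1) < cfg$p_rewire_gen) {
        cand <- setdiff(present, pref)
        if (length(cand) > 0) {
          # shift by the minimum before exponentiating: the selection law is
          # invariant and the closest candidate keeps weight 1 even when
          # tau is far below the distance scale
          w <- if (is.infinite(cfg$tau)) rep(1, length(cand))
               else exp(-(d_min_all[cand] - min(d_min_all[cand])) / cfg$tau)
          realized <- c(realized, sample(cand, 1, prob = w))
        }
      }
      taken <- unlist(lapply(realized, function(s) {
        inds <- inds_by_frag_sp[[paste(f, s, sep = ".")]]
        take <- inds[stats::runif(length(inds)) < cfg$p_individual]
        if (length(take) == 0) take <- sample(inds, 1)
        take
      }))
      if (length(taken) > 0) {
        cells[[oi]] <- c(cells[[oi]], list(taken))
      }
    }
  }
  cells_ind <- lapply(cells, function(x) unique(unlist(x)))
  inter <- data.frame(
    otu_id = rep(otus, lengths(cells_ind)),
    individual_id = unlist(cells_ind),
    stringsAsFactors = FALSE)
  dataset <- build_dataset(inter, individuals, taxonomy, tree)
  truth <- data.frame(otu_id = otus, stringsAsFactors = FALSE)
  truth$preferred <- truth_pref
  truth$tau <- cfg$tau
  truth$p_rewire_gen <- cfg$p_rewire_gen
  list(dataset = dataset, truth = truth)
}

#' Generate a complete synthetic community dataset with ground truth
#'
#' Convenience wrapper running [generate_phylogeny()],
#' [generate_landscape()] and [generate_interactions()] from one seed.
#'
#' @param cfg a [synthetic_config()] (defaults used if missing).
#' @param seed integer seed controlling all randomness.
#' @return List with `dataset`, `truth`, `tree`, `taxonomy`, `cfg`, `seed`.
#' @export
generate_community <- function(cfg = synthetic_config(), seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  phy <- generate_phylogeny(cfg)
  individuals <- generate_landscape(cfg, phy$taxonomy)
  gen <- generate_interactions(cfg, individuals, phy$taxonomy, phy$tree)
  c(gen, list(tree = phy$tree, taxonomy = phy$taxonomy, cfg = cfg, seed = seed))
}

#' Ground-truth (oracle) host classification of a synthetic community
#'
#' Builds a `preference_table` directly from the generator's ground truth
#' instead of estimating it with [classify_hosts()]: true preferred hosts are
#' `preferred`, co-occurring species that harbored the OTU are
#' `nonpreferred`, the rest `undetermined`. Useful for calibration studies of
#' [constraint_test()] -- with oracle classification the observed rewired
#' hosts are, under `tau = Inf`, exact uniform draws from the null candidate
#' pool, so the test's type-I error can be checked free of classification
#' noise -- and as the reference when scoring [classify_hosts()] recovery.
#'
#' @param sim output of [generate_community()].
#' @return A `preference_table` (see [classify_hosts()]; `ratio` is the
#'   empirical realization fraction, `low_support` always `FALSE`).
#' @export
truth_preference_table <- function(sim) {
  counts <- cooccurrence_counts(sim$dataset)
  truth <- stats::setNames(sim$truth$preferred, sim$truth$otu_id)
  is_pref <- mapply(function(o, s) s %in% truth[[o]],
                    counts$otu_id, counts$species)
  cls <- ifelse(is_pref, "preferred",
                ifelse(counts$n_realized >= 1, "nonpreferred", "undetermined"))
  out <- cbind(counts,
               data.frame(ratio = counts$n_realized / counts$n_potential,
                          class = cls, low_support = FALSE))
  rownames(out) <- NULL
  class(out) <- c("preference_table", "data.frame")
  out
}

#' Write a synthetic community to the standard input files
#'
#' Writes `interactions.csv`, `individuals.csv`, `taxonomy.csv`,
#' `phylogeny.nwk`, plus `ground_truth.csv` (true preferred hosts, one row
#' per OTU-species pair) and `config.yaml`.
#'
#' @param sim output of [generate_community()].
#' @param dir output directory.
#' @return Invisibly, the output directory.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(sim$dataset, dir)
  gt <- do.call(rbind, lapply(seq_len(nrow(sim$truth)), function(i) {
    data.frame(otu_id = sim$truth$otu_id[i],
               preferred_species = sim$truth$preferred[[i]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- sim$cfg
  cfg$n_preferred_per_otu <- as.integer(cfg$n_preferred_per_otu)
  yaml::write_yaml(c(unclass(cfg), list(seed = sim$seed)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
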