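#' Read a multi-fragment plant-mycorrhizal community dataset
#'
#' Assembles the pipeline's single input bundle from four plain-text files:
#' a long-format interaction table (one row per detection of a fungal OTU in
#' the roots of one plant individual), an individual registry, a species
#' taxonomy and a phylogeny of the plant species.
#'
#' @param interactions_path CSV with columns `otu_id`, `individual_id`; one
#'   row per detected OTU-individual pair (presence/absence only).
#' @param individuals_path CSV with columns `individual_id`, `fragment_id`,
#'   `species`; one row per sampled plant individual.
#' @param taxonomy_path CSV with columns `species`, `family`.
#' @param newick_path Newick tree with branch lengths; tip labels must cover
#'   every species in the taxonomy (exact match after trimming whitespace).
#'
#' @details
#' Validation is strict: duplicated individual ids, interactions that
#' reference unknown individuals, species missing from the taxonomy or from
#' the tree, and trees without branch lengths are all hard errors. Species
#' absent from the tree are never dropped silently because that would bias
#' the candidate pool of the phylogenetic null model downstream.
#'
#' Within each fragment, the incidence matrix keeps one column per sampled
#' individual (including individuals with no detections) and one row per OTU
#' detected in at least one individual of that fragment; an OTU is "present
#' in a fragment" only if detected there.
#'
#' @return A `community_dataset`: a list with elements
#'   \describe{
#'     \item{fragments}{named list of binary OTU x individual incidence
#'       matrices, one per fragment.}
#'     \item{individuals}{data.frame `individual_id`, `fragment_id`, `species`.}
#'     \item{taxonomy}{data.frame `species`, `family`.}
#'     \item{tree}{the `phylo` object.}
#'     \item{phylo_dist}{cophenetic distance matrix over the taxonomy species,
#'       in the branch-length units of the tree.}
#'   }
#' @seealso [cophenetic_matrix()], [aggregate_to_species()], [write_dataset()]
#' @export
read_dataset <- function(interactions_path, individuals_path, taxonomy_path,
                         newick_path) {
  for (p in c(interactions_path, individuals_path, taxonomy_path, newick_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  inter <- read_checked_csv(interactions_path, c("otu_id", "individual_id"))
  indiv <- read_checked_csv(individuals_path,
                            c("individual_id", "fragment_id", "species"))
  taxo  <- read_checked_csv(taxonomy_path, c("species", "family"))
  tree  <- ape::read.tree(newick_path)
  if (is.null(tree)) stop("could not parse Newick tree: ", newick_path,
                          call. = FALSE)
  tree$tip.label <- trimws(tree$tip.label)
  build_dataset(inter, indiv, taxo, tree)
}

read_checked_csv <- function(path, cols) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[cols]
  for (j in seq_along(df)) df[[j]] <- trimws(as.character(df[[j]]))
  bad <- which(!stats::complete.cases(df) | apply(df == "", 1, any))
  if (length(bad) > 0) {
    stop("file '", path, "': empty or missing field at data line ", bad[1],
         call. = FALSE)
  }
  df
}

# Assemble and validate a community_dataset from in-memory tables.
build_dataset <- function(inter, indiv, taxo, tree) {
  dup <- indiv$individual_id[duplicated(indiv$individual_id)]
  if (length(dup) > 0) {
    stop("duplicated individual_id in individual registry: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  dup_sp <- taxo$species[duplicated(taxo$species)]
  if (length(dup_sp) > 0) {
    stop("species mapped to more than one row in taxonomy: ",
         paste(unique(dup_sp), collapse = ", "), call. = FALSE)
  }
  unknown_ind <- setdiff(inter$individual_id, indiv$individual_id)
  if (length(unknown_ind) > 0) {
    stop("interaction table references unknown individual_id(s): ",
         paste(sort(unknown_ind), collapse = ", "), call. = FALSE)
  }
  unknown_sp <- setdiff(indiv$species, taxo$species)
  if (length(unknown_sp) > 0) {
    stop("individual registry references species missing from taxonomy: ",
         paste(sort(unknown_sp), collapse = ", "), call. = FALSE)
  }

  phylo_dist <- cophenetic_matrix(tree)
  not_in_tree <- setdiff(taxo$species, rownames(phylo_dist))
  if (length(not_in_tree) > 0) {
    stop("species missing from the phylogeny: ",
         paste(sort(not_in_tree), collapse = ", "), call. = FALSE)
  }
  phylo_dist <- phylo_dist[taxo$species, taxo$species, drop = FALSE]

  fragments <- lapply(split(indiv, indiv$fragment_id), function(reg) {
    ids <- reg$individual_id
    sub <- inter[inter$individual_id %in% ids, , drop = FALSE]
    otus <- sort(unique(sub$otu_id))
    mat <- matrix(0L, nrow = length(otus), ncol = length(ids),
                  dimnames = list(otus, ids))
    if (nrow(sub) > 0) mat[cbind(sub$otu_id, sub$individual_id)] <- 1L
    mat
  })
  fragments <- fragments[order(names(fragments))]

  structure(
    list(fragments = fragments,
         individuals = indiv[order(indiv$fragment_id, indiv$individual_id), ,
                             drop = FALSE],
         taxonomy = taxo[order(taxo$species), , drop = FALSE],
         tree = tree,
         phylo_dist = phylo_dist),
    class = "community_dataset"
  )
}

#' @export
print.community_dataset <- function(x, ...) {
  n_otu <- length(unique(unlist(lapply(x$fragments, rownames))))
  cat("Plant-mycorrhizal community dataset\n")
  cat("  fragments:   ", length(x$fragments), "\n", sep = "")
  cat("  individuals: ", nrow(x$individuals), "\n", sep = "")
  cat("  species:     ", nrow(x$taxonomy), " in ",
      length(unique(x$taxonomy$family)), " families\n", sep = "")
  cat("  fungal OTUs: ", n_otu, " (detected in >= 1 fragment)\n", sep = "")
  cat("  presences:  ", sum(vapply(x$fragments, nrow, 0L)),
      " (OTU x fragment)\n", sep = "")
  invisible(x)
}

#' Write a community dataset back to its four input files
#'
#' Inverse of [read_dataset()]: writes `interactions.csv`, `individuals.csv`,
#' `taxonomy.csv` and `phylogeny.nwk` into `dir`. Reading them back yields an
#' identical dataset (distances to numerical round-off).
#'
#' @param dataset a `community_dataset`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the four file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "community_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$fragments, function(mat) {
    idx <- which(mat == 1L, arr.ind = TRUE)
    data.frame(otu_id = rownames(mat)[idx[, 1]],
               individual_id = colnames(mat)[idx[, 2]],
               stringsAsFactors = FALSE)
  })
  inter <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  inter <- inter[order(inter$otu_id, inter$individual_id), , drop = FALSE]
  paths <- file.path(dir, c("interactions.csv", "individuals.csv",
                            "taxonomy.csv", "phylogeny.nwk"))
  utils::write.csv(inter, paths[1], row.names = FALSE, quote = FALSE)
  indiv <- dataset$individuals
  names(indiv) <- c("individual_id", "fragment_id", "species")
  utils::write.csv(indiv, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$taxonomy, paths[3], row.names = FALSE, quote = FALSE)
  ape::write.tree(dataset$tree, paths[4])
  invisible(paths)
}

#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' Distance between two tips is the sum of branch lengths along the path
#' connecting them, in the branch-length units of the tree (Myr for a
#' time-calibrated phylogeny). Computed with `ape::cophenetic.phylo` after
#' validating that the tree has branch lengths on all edges and no duplicate
#' tip labels.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = tip labels.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
#' cophenetic_matrix(tr)["A", "B"]  # 2
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object",
                                     call. = FALSE)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("tree must have a branch length on every edge", call. = FALSE)
  }
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) {
    stop("duplicated tip label(s) in tree: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Collapse an individual-level fragment network to the species level
#'
#' Species-level incidence is the logical OR over the individuals of each
#' species: entry (OTU, species) is 1 iff at least one individual of that
#' species in the fragment carries the OTU. Columns cover every species with
#' at least one sampled individual in the fragment (species "present in the
#' fragment"), whether or not it carries any OTU.
#'
#' @param fragment binary OTU x individual incidence matrix (one fragment).
#' @param individuals individual registry data.frame (`individual_id`,
#'   `fragment_id`, `species`) resolving every column.
#' @return Binary OTU x species matrix.
#' @export
aggregate_to_species <- function(fragment, individuals) {
  ids <- colnames(fragment)
  sp <- individuals$species[match(ids, individuals$individual_id)]
  if (anyNA(sp)) {
    stop("unresolvable individual_id(s): ",
         paste(ids[is.na(sp)], collapse = ", "), call. = FALSE)
  }
  species <- sort(unique(sp))
  out <- matrix(0L, nrow = nrow(fragment), ncol = length(species),
                dimnames = list(rownames(fragment), species))
  for (s in species) {
    cols <- fragment[, sp == s, drop = FALSE]
    out[, s] <- as.integer(rowSums(cols) > 0)
  }
  out
}

# Species-level networks for every fragment, as a named list.
species_networks <- function(dataset) {
  lapply(dataset$fragments, aggregate_to_species,
         individuals = dataset$individuals)
}
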