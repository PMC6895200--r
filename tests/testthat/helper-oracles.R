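# Independent brute-force oracles and small in-code fixtures.

# Path-sum cophenetic distance, computed from the edge table alone:
# walk each tip to the root, then add branch lengths up to the deepest
# shared node of the two walks.
oracle_cophenetic <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  walk <- function(node) {        # nodes from tip to root
    path <- node
    while (node != root) {
      node <- parent[node]
      path <- c(path, node)
    }
    path
  }
  d <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip - 1)) {
    pi <- walk(i)
    for (j in (i + 1):n_tip) {
      pj <- walk(j)
      mrca <- intersect(pi, pj)[1]
      up <- function(p) sum(plen[p[seq_len(which(p == mrca) - 1)]])
      d[i, j] <- d[j, i] <- up(pi) + up(pj)
    }
  }
  d
}

# Set-enumeration partition oracle: builds interaction pair lists cell by
# cell and counts union/intersection sizes directly (Whittaker form).
oracle_partition <- function(net_a, net_b) {
  pairs_of <- function(net) {
    out <- character(0)
    for (i in seq_len(nrow(net))) for (j in seq_len(ncol(net))) {
      if (net[i, j] == 1) {
        out <- c(out, paste0(colnames(net)[j], "~", rownames(net)[i]))
      }
    }
    out
  }
  whit <- function(a, b) {
    if (length(a) == 0 && length(b) == 0) return(NA_real_)
    S <- length(union(a, b))
    S / ((length(a) + length(b)) / 2) - 1
  }
  A <- pairs_of(net_a); B <- pairs_of(net_b)
  wn <- whit(A, B)
  sp <- intersect(colnames(net_a), colnames(net_b))
  ot <- intersect(rownames(net_a), rownames(net_b))
  if (length(sp) == 0 || length(ot) == 0) {
    os <- NA_real_
  } else {
    keep <- function(p) {
      parts <- strsplit(p, "~", fixed = TRUE)
      p[vapply(parts, function(x) x[1] %in% sp && x[2] %in% ot, TRUE)]
    }
    a2 <- keep(A); b2 <- keep(B)
    os <- whit(a2, b2)
    if (is.na(os)) os <- 0
  }
  c(beta_wn = wn, beta_os = os,
    beta_st = if (is.na(os)) NA_real_ else wn - os)
}

# Random toy species-level network with named rows (OTUs) and columns.
random_toy_net <- function(n_otu, n_sp, fill = 0.4,
                           otus = sprintf("o%d", seq_len(n_otu)),
                           species = sprintf("S%d", seq_len(n_sp))) {
  m <- matrix(as.integer(runif(n_otu * n_sp) < fill), n_otu, n_sp,
              dimnames = list(otus, species))
  if (sum(m) == 0) m[sample(length(m), 1)] <- 1L
  m
}

# Two-fragment, four-species fixture written as the four input files.
write_toy_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(
    otu_id = c("o1", "o1", "o2", "o2", "o3"),
    individual_id = c("a1", "a2", "a2", "b1", "b2")),
    file.path(dir, "interactions.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(
    individual_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    fragment_id = rep(c("fA", "fB"), each = 3),
    species = c("S1", "S2", "S2", "S3", "S4", "S1")),
    file.path(dir, "individuals.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(species = c("S1", "S2", "S3", "S4"),
                       family = c("F1", "F1", "F2", "F2")),
    file.path(dir, "taxonomy.csv"), row.names = FALSE, quote = FALSE)
  writeLines("((S1:1,S2:1):2,(S3:1.5,S4:1.5):1.5);",
             file.path(dir, "phylogeny.nwk"))
  dir
}

# Small fast synthetic configuration for pipeline-level tests.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_fragments = 5, n_individuals_per_fragment = 8,
         n_species = 10, n_families = 4, n_otus = 25),
    list(...))
  do.call(synthetic_config, args)
}
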