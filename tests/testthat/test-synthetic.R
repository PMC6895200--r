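test_that("synthetic phylogeny keeps families monophyletic and shallow", {
  set.seed(51)
  phy <- generate_phylogeny(synthetic_config())
  expect_equal(length(phy$tree$tip.label), 28)
  expect_equal(length(unique(phy$taxonomy$family)), 13)
  expect_true(all(table(phy$taxonomy$family) >= 1))
  d <- cophenetic_matrix(phy$tree)
  fam <- setNames(phy$taxonomy$family, phy$taxonomy$species)
  same <- outer(fam[rownames(d)], fam[colnames(d)], "==") & upper.tri(d)
  diff_fam <- !outer(fam[rownames(d)], fam[colnames(d)], "==") & upper.tri(d)
  expect_lt(max(d[same]), min(d[diff_fam]))   # within < between, always
  expect_true(all(phy$tree$edge.length > 0))

  set.seed(52)
  tiny <- generate_phylogeny(synthetic_config(n_species = 2, n_families = 2,
                                              n_otus = 5))
  expect_equal(ape::Ntip(tiny$tree), 2)
  expect_equal(tiny$tree$Nnode, 1)            # two tips joined at the root
})

test_that("landscape honours sampling design and determinism", {
  cfg <- synthetic_config()
  set.seed(61)
  phy <- generate_phylogeny(cfg)
  set.seed(62)
  land1 <- generate_landscape(cfg, phy$taxonomy)
  set.seed(62)
  land2 <- generate_landscape(cfg, phy$taxonomy)
  expect_identical(land1, land2)
  expect_equal(nrow(land1), 225)              # 15 fragments x 15 individuals
  expect_equal(length(unique(land1$fragment_id)), 15)
  n_sp <- tapply(land1$species, land1$fragment_id, function(x) length(unique(x)))
  expect_true(all(n_sp >= 2))

  # full occupancy with a huge roster covers every species
  cfg_full <- small_cfg(species_occupancy = 1,
                        n_individuals_per_fragment = 400)
  set.seed(63)
  land3 <- generate_landscape(cfg_full, phy$taxonomy[1:10, ])
  expect_setequal(unique(land3$species), phy$taxonomy$species[1:10])
})

test_that("generated interactions respect the preference ground truth", {
  # no rewiring: every species-level interaction involves a true preferred host
  sim0 <- generate_community(small_cfg(p_rewire_gen = 0), seed = 71)
  truth <- setNames(sim0$truth$preferred, sim0$truth$otu_id)
  nets <- lapply(sim0$dataset$fragments, aggregate_to_species,
                 individuals = sim0$dataset$individuals)
  for (net in nets) {
    for (o in rownames(net)) {
      hosts <- colnames(net)[net[o, ] == 1L]
      expect_true(all(hosts %in% truth[[o]]))
    }
  }
  # with rewiring, at most one non-preferred host per OTU per fragment
  sim1 <- generate_community(small_cfg(p_rewire_gen = 1), seed = 72)
  truth1 <- setNames(sim1$truth$preferred, sim1$truth$otu_id)
  nets1 <- lapply(sim1$dataset$fragments, aggregate_to_species,
                  individuals = sim1$dataset$individuals)
  extra <- unlist(lapply(nets1, function(net) {
    vapply(rownames(net), function(o) {
      sum(!(colnames(net)[net[o, ] == 1L] %in% truth1[[o]]))
    }, 0L)
  }))
  expect_true(all(extra <= 1))
  expect_gt(sum(extra), 0)
})

test_that("the rewiring kernel concentrates on close relatives as tau shrinks", {
  # one fragment covering all species; forced rewiring; single preferred host
  cfg <- synthetic_config(n_fragments = 1, n_individuals_per_fragment = 150,
                          n_species = 12, n_families = 4, n_otus = 800,
                          species_occupancy = 1, p_rewire_gen = 1,
                          n_preferred_per_otu = 1, tau = 1e-3)
  sim <- generate_community(cfg, seed = 81)
  d <- sim$dataset$phylo_dist
  truth <- setNames(sim$truth$preferred, sim$truth$otu_id)
  net <- aggregate_to_species(sim$dataset$fragments[[1]],
                              sim$dataset$individuals)
  present <- colnames(net)
  hits <- misses <- 0L
  for (o in rownames(net)) {
    pref <- truth[[o]]
    rewired <- setdiff(colnames(net)[net[o, ] == 1L], pref)
    if (length(rewired) != 1 || !all(pref %in% present)) next
    cand <- setdiff(present, pref)
    dmin <- apply(d[cand, pref, drop = FALSE], 1, min)
    closest <- names(dmin)[dmin <= min(dmin) + 1e-4]  # equidistant sister tips
    if (rewired %in% closest) hits <- hits + 1L else misses <- misses + 1L
  }
  expect_gt(hits, 100)
  expect_equal(misses, 0L)       # tau -> 0: always the closest candidate
})

test_that("tau = Inf selects rewired hosts uniformly", {
  cfg <- synthetic_config(n_fragments = 1, n_individuals_per_fragment = 150,
                          n_species = 12, n_families = 4, n_otus = 10000,
                          species_occupancy = 1, p_rewire_gen = 1,
                          n_preferred_per_otu = 1, tau = Inf)
  sim <- generate_community(cfg, seed = 82)
  truth <- setNames(sim$truth$preferred, sim$truth$otu_id)
  net <- aggregate_to_species(sim$dataset$fragments[[1]],
                              sim$dataset$individuals)
  picks <- character(0)
  anchors <- character(0)
  for (o in rownames(net)) {
    rewired <- setdiff(colnames(net)[net[o, ] == 1L], truth[[o]])
    if (length(rewired) == 1) {
      picks <- c(picks, rewired)
      anchors <- c(anchors, truth[[o]])
    }
  }
  # condition on one anchor host: candidates are the other 11 species
  anchor <- names(sort(table(anchors), decreasing = TRUE))[1]
  sel <- picks[anchors == anchor]
  expect_gt(length(sel), 400)
  gof <- chisq.test(table(sel))
  expect_gt(gof$p.value, 0.01)
})

test_that("occupancy drives the turnover share of network dissimilarity", {
  ratios <- sapply(c(0.45, 0.95), function(occ) {
    mean(sapply(1:5, function(s) {
      sim <- generate_community(synthetic_config(species_occupancy = occ,
                                                 n_otus = 60), seed = s)
      attr(partition_all(sim$dataset), "mean_ratio")
    }))
  })
  expect_lt(ratios[2], ratios[1])   # saturated landscapes rewire, not turn over
})

test_that("ground-truth classification feeds the oracle preference table", {
  sim <- generate_community(small_cfg(), seed = 91)
  pt <- truth_preference_table(sim)
  expect_s3_class(pt, "preference_table")
  truth <- setNames(sim$truth$preferred, sim$truth$otu_id)
  pref_rows <- pt[pt$class == "preferred", ]
  expect_true(all(mapply(function(o, s) s %in% truth[[o]],
                         pref_rows$otu_id, pref_rows$species)))
  np <- pt[pt$class == "nonpreferred", ]
  expect_true(all(np$n_realized >= 1))
})
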