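test_that("toy fixture loads into a validated dataset", {
  dir <- write_toy_files(withr::local_tempdir())
  ds <- read_dataset(file.path(dir, "interactions.csv"),
                     file.path(dir, "individuals.csv"),
                     file.path(dir, "taxonomy.csv"),
                     file.path(dir, "phylogeny.nwk"))
  expect_s3_class(ds, "community_dataset")
  expect_named(ds$fragments, c("fA", "fB"))
  expect_equal(nrow(ds$taxonomy), 4)
  expect_equal(nrow(ds$individuals), 6)
  # fragment matrices: all sampled individuals as columns, detected OTUs as rows
  expect_equal(dim(ds$fragments$fA), c(2, 3))   # o1, o2 detected in fA
  expect_equal(sort(rownames(ds$fragments$fB)), c("o2", "o3"))
  expect_equal(unname(ds$fragments$fA["o1", c("a1", "a2", "a3")]), c(1L, 1L, 0L))
})

test_that("input validation names the offending records", {
  dir <- write_toy_files(withr::local_tempdir())
  paths <- file.path(dir, c("interactions.csv", "individuals.csv",
                            "taxonomy.csv", "phylogeny.nwk"))
  # interaction referencing an unknown individual
  inter <- read.csv(paths[1])
  inter <- rbind(inter, data.frame(otu_id = "o9", individual_id = "X9"))
  bad <- file.path(dir, "bad_inter.csv")
  write.csv(inter, bad, row.names = FALSE)
  expect_error(read_dataset(bad, paths[2], paths[3], paths[4]), "X9")

  # duplicated individual id
  ind <- read.csv(paths[2])
  ind <- rbind(ind, ind[1, ])
  bad2 <- file.path(dir, "bad_ind.csv")
  write.csv(ind, bad2, row.names = FALSE)
  expect_error(read_dataset(paths[1], bad2, paths[3], paths[4]), "duplicated")

  # species missing from the tree are a hard error listing the names
  writeLines("((S1:1,S2:1):2,S3:3);", file.path(dir, "small_tree.nwk"))
  expect_error(read_dataset(paths[1], paths[2], paths[3],
                            file.path(dir, "small_tree.nwk")), "S4")

  # tree without branch lengths
  writeLines("((S1,S2),(S3,S4));", file.path(dir, "nolen.nwk"))
  expect_error(read_dataset(paths[1], paths[2], paths[3],
                            file.path(dir, "nolen.nwk")), "branch length")

  # missing required column
  write.csv(data.frame(x = 1), file.path(dir, "wrong.csv"), row.names = FALSE)
  expect_error(read_dataset(file.path(dir, "wrong.csv"), paths[2], paths[3],
                            paths[4]), "otu_id")
})

test_that("cophenetic distances are exact path sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  d <- cophenetic_matrix(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 6)
  expect_equal(d["B", "C"], 6)
  expect_equal(unname(diag(d)), rep(0, 3))

  star <- ape::read.tree(text = "(A:5,B:5,C:5);")
  ds <- cophenetic_matrix(star)
  expect_equal(unname(ds[upper.tri(ds)]), rep(10, 3))

  dup <- ape::read.tree(text = "((A:1,A:1):2,C:3);")
  expect_error(cophenetic_matrix(dup), "duplicated tip")
})

test_that("cophenetic matrix agrees with the path-sum oracle on random trees", {
  set.seed(401)
  for (i in 1:50) {
    tr <- ape::rtree(sample(5:10, 1))
    expect_equal(cophenetic_matrix(tr)[tr$tip.label, tr$tip.label],
                 oracle_cophenetic(tr), tolerance = 1e-12)
  }
})

test_that("species aggregation is an OR over individuals", {
  frag <- matrix(c(1L, 0L, 1L, 0L, 0L, 1L), nrow = 2,
                 dimnames = list(c("o1", "o2"), c("i1", "i2", "i3")))
  reg <- data.frame(individual_id = c("i1", "i2", "i3"),
                    fragment_id = "f", species = c("S", "S", "T"))
  net <- aggregate_to_species(frag, reg)
  expect_equal(unname(net["o1", ]), c(1L, 0L))     # i1,i2 collapse to S
  expect_equal(unname(net["o2", ]), c(0L, 1L))
  expect_lte(sum(net), sum(frag))

  # OTU on one individual of each of 2 species -> species-level row sum 2
  frag2 <- matrix(c(1L, 1L, 0L), nrow = 1,
                  dimnames = list("o1", c("i1", "i2", "i3")))
  reg2 <- data.frame(individual_id = c("i1", "i2", "i3"),
                     fragment_id = "f", species = c("S", "T", "T"))
  expect_equal(sum(aggregate_to_species(frag2, reg2)["o1", ]), 2L)

  # empty matrix stays empty
  empty <- matrix(integer(0), nrow = 0, ncol = 2,
                  dimnames = list(NULL, c("i1", "i2")))
  expect_equal(dim(aggregate_to_species(empty, reg[1:2, ])), c(0L, 1L))

  # monotone: adding an individual-level detection never removes a cell
  set.seed(7)
  for (rep in 1:20) {
    f1 <- random_toy_net(4, 6, fill = 0.3,
                         species = sprintf("i%d", 1:6))
    regs <- data.frame(individual_id = sprintf("i%d", 1:6), fragment_id = "f",
                       species = sample(c("S", "T", "U"), 6, replace = TRUE))
    n1 <- aggregate_to_species(f1, regs)
    f2 <- f1
    zero <- which(f2 == 0L)
    if (length(zero) > 0) f2[sample(zero, 1)] <- 1L
    n2 <- aggregate_to_species(f2, regs)
    expect_true(all(n2 >= n1))
    expect_identical(aggregate_to_species(f1, regs), n1)  # idempotent input
  }
})

test_that("write/read round trip preserves the dataset", {
  sim <- generate_community(small_cfg(), seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir)
  ds2 <- read_dataset(file.path(dir, "interactions.csv"),
                      file.path(dir, "individuals.csv"),
                      file.path(dir, "taxonomy.csv"),
                      file.path(dir, "phylogeny.nwk"))
  expect_identical(lapply(ds2$fragments, unname),
                   lapply(sim$dataset$fragments, unname))
  expect_identical(ds2$fragments, sim$dataset$fragments)
  expect_equal(ds2$taxonomy, sim$dataset$taxonomy, ignore_attr = TRUE)
  expect_equal(ds2$phylo_dist, sim$dataset$phylo_dist, tolerance = 1e-12)
})
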