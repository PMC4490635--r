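test_that("species trees have kingdom-level clades and community flags", {
  cfg <- sim_config(n_bacteria = 2, n_archaea = 2, community_bacteria = 2,
                    community_archaea = 2, n_families = 4, n_transfers = 0,
                    block_sizes = integer(0), n_rate_decoys = 0, seed = 1)
  tr <- simulate_species_tree(cfg)
  expect_setequal(tr$tip.label, c("Bac01", "Bac02", "Arc01", "Arc02"))
  expect_setequal(tree_splits(tr), "Bac01,Bac02")   # forced (2+2) shape
  cfg17 <- sim_config(seed = 3)   # full-scale default: 17 genomes, 8 members
  tr17 <- simulate_species_tree(cfg17)
  md <- attr(tr17, "metadata")
  expect_equal(nrow(md), 17)
  expect_equal(sum(md$in_community), 8)
  expect_true(ape::is.monophyletic(tr17, md$genome_id[md$kingdom == "bacteria"]))
  # maximum divergence respects the configured height
  expect_equal(max(ape::cophenetic.phylo(tr17)), cfg17$tree_height,
               tolerance = 1e-6)
  # determinism
  expect_identical(write_newick(simulate_species_tree(cfg17)),
                   write_newick(tr17))
})

test_that("zero-length branches copy the parent sequence", {
  tr <- read_newick("(A:0,B:0.4);")
  rows <- evolve_family(tr, n_sites = 100, seed = 5)
  tr2 <- read_newick("(A:0,B:0);")
  rows2 <- evolve_family(tr2, n_sites = 100, seed = 5)
  expect_equal(rows2[["A"]], rows2[["B"]])
})

test_that("sequence divergence matches the closed-form expectation", {
  m <- dayhoff_model()
  t_tot <- 0.2
  tr <- read_newick("(A:0.1,B:0.1);")
  rows <- evolve_family(tr, m, n_sites = 10000, seed = 6)
  a <- strsplit(rows[["A"]], "")[[1]]; b <- strsplit(rows[["B"]], "")[[1]]
  obs <- mean(a != b)
  P <- prob_matrix(m, t_tot)
  expected <- 1 - sum(m$bf * diag(P))
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("saturated branches return stationary residue frequencies", {
  m <- dayhoff_model()
  tr <- read_newick("(A:10,B:10);")
  rows <- evolve_family(tr, m, n_sites = 10000, seed = 7)
  freq <- table(factor(strsplit(rows[["A"]], "")[[1]], levels = m$levels))
  chi <- sum((as.numeric(freq) - 10000 * m$bf)^2 / (10000 * m$bf))
  expect_lt(chi, qchisq(0.999, df = 19))
})

test_that("planted transfers regraft the recipient next to the donor", {
  sp <- read_newick(paste0("((B1:0.4,B2:0.4):0.35,",
                           "((A1:0.3,A2:0.3):0.2,A3:0.5):0.25);"))
  gt <- plant_transfer(sp, donor = "B1", recipient = "A1",
                       attach_height = 0.1)
  expect_setequal(gt$tip.label, sp$tip.label)
  # A1 now clusters with B1 inside the bacterial side
  expect_true("A1,B1" %in% tree_splits(gt) ||
                "A2,A3" %in% tree_splits(gt))
  expect_true(ape::is.monophyletic(gt, c("A1", "B1")))
  # still ultrametric
  d <- ape::node.depth.edgelength(gt)
  tipd <- d[seq_along(gt$tip.label)]
  expect_lt(diff(range(tipd)), 1e-8)
  # invalid height errors
  expect_error(plant_transfer(sp, "B1", "A1", attach_height = 5), "within")
})

test_that("simulated communities are deterministic and complete", {
  cfg <- sim_config(n_bacteria = 3, n_archaea = 3, community_bacteria = 3,
                    community_archaea = 3, n_families = 10, n_sites = 50,
                    n_transfers = 2, block_sizes = 2L, n_rate_decoys = 1,
                    seed = 11)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$genomes[["Bac01"]]$proteins$residues,
                   s2$genomes[["Bac01"]]$proteins$residues)
  expect_identical(s1$truth, s2$truth)
  # every family present in every genome
  for (g in s1$genomes) expect_equal(nrow(g$proteins), 10)
  expect_equal(nrow(s1$truth), 10)
  # truth statuses add up
  expect_equal(sum(s1$truth$status == "transfer"), 2)
  expect_equal(sum(s1$truth$status == "rate_decoy"), 1)
  # block members share the event and contiguous + strand coordinates
  blk <- s1$truth[!is.na(s1$truth$block_id), ]
  expect_equal(nrow(blk), 2)
  expect_equal(length(unique(blk$donor)), 1)
  expect_equal(length(unique(blk$recipient)), 1)
  expect_true(all(blk$strand == "+"))
  idx <- match(blk$family_id, s1$truth$family_id)
  expect_equal(diff(sort(idx)), 1)
  # decoys change branch lengths only: topology equals the species tree
  expect_true(all(is.na(s1$truth$accelerated) |
                    s1$truth$status == "rate_decoy"))
})

test_that("emitted communities round-trip through the package loaders", {
  cfg <- sim_config(n_bacteria = 2, n_archaea = 2, community_bacteria = 2,
                    community_archaea = 2, n_families = 5, n_sites = 40,
                    n_transfers = 1, block_sizes = integer(0),
                    n_rate_decoys = 0, seed = 13)
  sim <- simulate_community(cfg)
  dir <- tempfile(); dir.create(dir)
  emit_community(sim, dir)
  comm <- load_community(file.path(dir, "metadata.tsv"))
  expect_length(comm, 4)
  expect_equal(comm[["Arc01"]]$proteins$residues,
               sim$genomes[["Arc01"]]$proteins$residues)
  # GFF3 coordinates attached
  expect_true(all(!is.na(comm[["Arc01"]]$proteins$start)))
  expect_equal(comm[["Arc01"]]$proteins$strand,
               sim$genomes[["Arc01"]]$proteins$strand)
  # truth TSV round-trips losslessly
  back <- read_tsv_headered(file.path(dir, "truth.tsv"))
  expect_equal(back$family_id, sim$truth$family_id)
  expect_equal(back$status, sim$truth$status)
  expect_equal(back$recipient, sim$truth$recipient)
  # species tree readable and complete
  sp <- species_tree(file.path(dir, "species_tree.nwk"),
                     sim$metadata$genome_id)
  expect_setequal(sp$tip.label, sim$metadata$genome_id)
})

test_that("null family genealogies equal the species tree topology", {
  cfg <- sim_config(n_bacteria = 3, n_archaea = 3, community_bacteria = 3,
                    community_archaea = 3, n_families = 6, n_sites = 30,
                    n_transfers = 1, block_sizes = integer(0),
                    n_rate_decoys = 1, seed = 17)
  sim <- simulate_community(cfg)
  # a planted event later recovered in the genealogy: recipient sequence
  # is closest to the donor's
  ev <- sim$truth[sim$truth$status == "transfer", ][1, ]
  rows <- vapply(sim$genomes, function(g) {
    g$proteins$residues[g$proteins$protein_id == ev$family_id]
  }, "")
  dist_to <- function(x, y) mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  drec <- vapply(setdiff(names(rows), ev$recipient), function(g) {
    dist_to(rows[[ev$recipient]], rows[[g]])
  }, 0)
  # the closest relative is on the donor's side of the tree (the donor
  # itself, or its sister when the graft sits above their split)
  donor_kingdom <- sim$metadata$kingdom[sim$metadata$genome_id == ev$donor]
  closest <- names(which.min(drec))
  expect_equal(sim$metadata$kingdom[sim$metadata$genome_id == closest],
               donor_kingdom)
  expect_lt(drec[[ev$donor]], max(drec))
})
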