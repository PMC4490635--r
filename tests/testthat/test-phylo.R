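test_that("Dayhoff transition matrices are stochastic, stationary, reversible", {
  m <- dayhoff_model()
  expect_equal(sum(m$bf), 1, tolerance = 1e-12)
  for (t in c(0.01, 0.1, 1, 10)) {
    P <- prob_matrix(m, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_lt(max(abs(as.numeric(m$bf %*% P) - m$bf)), 1e-10)
    expect_true(all(P >= 0))
  }
  # detailed balance pi_i q_ij = pi_j q_ji
  Qb <- m$Q * m$bf
  expect_lt(max(abs(Qb - t(Qb))), 1e-12)
  # mean rate one substitution/site
  expect_equal(-sum(m$bf * diag(m$Q)), 1, tolerance = 1e-12)
})

test_that("P(t) matches an independent matrix exponential", {
  m <- dayhoff_model()
  for (t in c(0.05, 0.5, 2)) {
    ref <- as.matrix(Matrix::expm(m$Q * t))
    expect_lt(max(abs(prob_matrix(m, t) - ref)), 1e-8)
  }
})

test_that("two-taxon likelihood matches the spectral closed form", {
  m <- dayhoff_model()
  set.seed(7)
  a <- paste(sample(m$levels, 80, TRUE), collapse = "")
  b <- paste(sample(m$levels, 80, TRUE), collapse = "")
  msa <- make_msa(c(A = a, B = b))
  sl <- tree_lnL(read_newick("(A:0.13,B:0.17);"), msa, m)
  P <- as.matrix(Matrix::expm(m$Q * 0.3))
  xa <- match(strsplit(a, "")[[1]], m$levels)
  xb <- match(strsplit(b, "")[[1]], m$levels)
  closed <- sum(log(m$bf[xa] * P[cbind(xa, xb)]))
  expect_equal(sl$lnl, closed, tolerance = 1e-8)
  # t = 0 degenerate cases
  same <- make_msa(c(A = "R", B = "R"))
  sl0 <- tree_lnL(read_newick("(A:0,B:0);"), same, m)
  expect_equal(sl0$lnl, log(m$bf[["R"]]), tolerance = 1e-4)
  diffc <- make_msa(c(A = "R", B = "W"))
  sld <- tree_lnL(read_newick("(A:0,B:0);"), diffc, m)
  expect_lt(sld$lnl, -15)   # effectively impossible, floored well below
})

test_that("pruning site likelihoods equal exhaustive summation on 4 taxa", {
  m <- dayhoff_model()
  set.seed(3)
  rows <- vapply(1:4, function(i) paste(sample(m$levels[1:20], 5, TRUE),
                                        collapse = ""), "")
  names(rows) <- c("A", "B", "C", "D")
  msa <- make_msa(rows)
  tr <- read_newick("((A:0.1,B:0.2):0.15,(C:0.12,D:0.3):0.05);")
  sl <- tree_lnL(tr, msa, m)
  x <- lapply(rows, function(r) match(strsplit(r, "")[[1]], m$levels))
  PA <- prob_matrix(m, 0.1); PB <- prob_matrix(m, 0.2)
  PC <- prob_matrix(m, 0.12); PD <- prob_matrix(m, 0.3)
  PI <- prob_matrix(m, 0.2)   # the two internal stems merge when unrooted
  brute <- vapply(1:5, function(s) {
    tot <- 0
    for (u in 1:20) for (v in 1:20) {
      tot <- tot + m$bf[u] * PA[u, x$A[s]] * PB[u, x$B[s]] *
        PI[u, v] * PC[v, x$C[s]] * PD[v, x$D[s]]
    }
    log(tot)
  }, 0)
  expect_lt(max(abs(sl$site_lnl - brute)), 1e-10)
  expect_equal(sl$lnl, sum(sl$site_lnl), tolerance = 1e-9)
})

test_that("gaps and X are treated as missing data", {
  m <- dayhoff_model()
  msa <- make_msa(c(A = "R-X", B = "RRR"))
  sl <- tree_lnL(read_newick("(A:0.1,B:0.1);"), msa, m)
  # columns 2 and 3: A contributes nothing, likelihood is just pi_R at B
  expect_equal(sl$site_lnl[2], log(m$bf[["R"]]), tolerance = 1e-9)
  expect_equal(sl$site_lnl[2], sl$site_lnl[3], tolerance = 1e-12)
})

test_that("ML pairwise distance matches a dense grid search", {
  m <- dayhoff_model()
  rows <- simulate_rows(read_newick("(A:0.2,B:0.2);"), 400, seed = 21)
  d <- ml_pair_distance(rows[["A"]], rows[["B"]], m)
  xa <- match(strsplit(rows[["A"]], "")[[1]], m$levels)
  xb <- match(strsplit(rows[["B"]], "")[[1]], m$levels)
  grid <- seq(1e-4, 2, by = 1e-4)
  nll <- vapply(grid, function(t) {
    P <- prob_matrix(m, t)
    -sum(log(m$bf[xa] * P[cbind(xa, xb)]))
  }, 0)
  expect_equal(d, grid[which.min(nll)], tolerance = 2e-4)
  expect_equal(ml_pair_distance(rows[["A"]], rows[["A"]], m), 0)
  # saturation cap
  set.seed(1)
  r1 <- random_peptide(60); r2 <- random_peptide(60)
  expect_gte(ml_pair_distance(r1, r2, m), 9.9)
  expect_error(ml_pair_distance("---", "AAA", m), "shared")
})

test_that("neighbor joining is exact on additive matrices", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(D)
  expect_setequal(tree_splits(tr), "C,D")
  expect_equal(sort(tr$edge.length), rep(1, 5))
  # random additive 6-taxon distances recover the generating topology
  set.seed(17)
  for (i in 1:5) {
    gen <- ape::rtree(6)
    gen$edge.length <- runif(nrow(gen$edge), 0.3, 1.5)
    D6 <- ape::cophenetic.phylo(gen)
    tr6 <- nj_tree(D6)
    expect_setequal(tree_splits(tr6), tree_splits(gen))
  }
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("branch-length optimization never decreases the likelihood", {
  m <- dayhoff_model()
  sp <- read_newick("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
  rows <- simulate_rows(sp, 150, seed = 8)
  msa <- make_msa(rows)
  start <- sp
  start$edge.length <- rep(0.5, nrow(start$edge))
  before <- tree_lnL(start, msa, m)$lnl
  opt <- optimize_branch_lengths(start, msa, m)
  expect_gte(opt$lnl, before)
  # two-taxon optimum equals the ML pairwise distance
  msa2 <- make_msa(rows[c("A", "B")])
  o2 <- optimize_branch_lengths(read_newick("(A:0.3,B:0.3);"), msa2, m)
  d2 <- ml_pair_distance(rows[["A"]], rows[["B"]], m)
  expect_equal(sum(o2$tree$edge.length), d2, tolerance = 1e-3)
})

test_that("likelihood is invariant under re-rooting", {
  m <- dayhoff_model()
  set.seed(11)
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length / 2
  rows <- simulate_rows(tr, 80, seed = 12)
  msa <- make_msa(rows)
  l1 <- tree_lnL(tr, msa, m)$lnl
  for (og in tr$tip.label[1:3]) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(tree_lnL(rr, msa, m)$lnl, l1, tolerance = 1e-8)
  }
})

test_that("ML search recovers a well-supported generating topology", {
  m <- dayhoff_model()
  gen <- read_newick(paste0("((A:0.2,B:0.2):0.15,((C:0.2,D:0.2):0.15,",
                            "(E:0.2,F:0.2):0.15):0.05);"))
  rows <- simulate_rows(gen, 300, seed = 13)
  fit <- ml_search(make_msa(rows), m)
  expect_setequal(tree_splits(fit$tree), tree_splits(gen))
  # an already-optimal start is a fixed point
  fit2 <- ml_search(make_msa(rows), m, start_tree = fit$tree)
  expect_setequal(tree_splits(fit2$tree), tree_splits(fit$tree))
  expect_equal(fit2$lnl, fit$lnl, tolerance = 1e-3)
})

test_that("majority-rule consensus contains exactly the > 0.5 splits", {
  set.seed(19)
  trees <- ape::rmtree(100, 8)
  # skew the sample so some splits exceed half
  base <- ape::rtree(8)
  for (i in 1:60) trees[[i]] <- base
  cons <- consensus_from_trees(trees)
  # independent recount oracle via prop.part
  pp <- ape::prop.part(trees)
  labs <- attr(pp, "labels"); ref <- sort(labs)[1]
  canon <- function(side) {
    if (ref %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = ",")
  }
  keys <- vapply(pp, function(cl) canon(labs[cl]), "")
  freq <- attr(pp, "number") / 100
  sz <- vapply(pp, function(cl) {
    s <- labs[cl]; if (ref %in% s) s <- setdiff(labs, s); length(s)
  }, 0L)
  expected <- unique(keys[freq > 0.5 & sz >= 2 & sz <= 6])
  expect_setequal(tree_splits(cons), expected)
  # supports are frequencies in [0, 1]
  sup <- suppressWarnings(as.numeric(cons$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0.5 & sup <= 1))
})

test_that("bootstrap consensus is seeded and supports lie in [0,1]", {
  m <- dayhoff_model()
  gen <- read_newick("((A:0.25,B:0.25):0.2,(C:0.25,D:0.25):0.1,(E:0.25,F:0.25):0.2);")
  rows <- simulate_rows(ape::root(gen, outgroup = "A", resolve.root = TRUE),
                        120, seed = 14)
  msa <- make_msa(rows)
  b1 <- bootstrap_consensus(msa, m, B = 10, seed = 5)
  b2 <- bootstrap_consensus(msa, m, B = 10, seed = 5)
  expect_identical(write_newick(b1$consensus), write_newick(b2$consensus))
  sup <- suppressWarnings(as.numeric(b1$consensus$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup > 0.5 & sup <= 1))
  # all-identical replicates give full support everywhere
  msa_id <- make_msa(simulate_rows(read_newick(
    "((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3);"), 200, seed = 15))
  bid <- bootstrap_consensus(msa_id, m, B = 5, seed = 6)
  supid <- suppressWarnings(as.numeric(bid$consensus$node.label))
  expect_true(all(stats::na.omit(supid) == 1))
})

test_that("species tree validation requires the exact genome set", {
  ids <- c("A", "B", "C", "D")
  tr <- species_tree("((A:1,B:1):1,(C:1,D:1):1);", ids)
  expect_setequal(tr$tip.label, ids)
  expect_error(species_tree("((A:1,B:1):1,C:1);", ids), "D")
  expect_error(species_tree("(((A:1,B:1):1,(C:1,D:1):1):1,E:1);", ids), "E")
})

test_that("an aligned rRNA FASTA yields the generating organism tree", {
  set.seed(29)
  gen <- read_newick(paste0("((G1:0.05,G2:0.05):0.04,((G3:0.05,G4:0.05)",
                            ":0.04,(G5:0.05,G6:0.05):0.04):0.02);"))
  dat <- phangorn::simSeq(gen, l = 800, type = "DNA")
  fa <- tempfile(fileext = ".fasta")
  ch <- as.character(dat)
  writeLines(paste0(">", rownames(ch), "\n",
                    apply(ch, 1, paste, collapse = "")), fa)
  tr <- species_tree(fa, sprintf("G%d", 1:6))
  expect_setequal(tree_splits(tr), tree_splits(gen))
  expect_true(ape::is.rooted(tr))
})

test_that("tree restriction preserves induced structure and is idempotent", {
  set.seed(23)
  tr <- ape::rtree(10)
  sub <- sort(tr$tip.label)[1:6]
  r1 <- restrict_tree(tr, sub)
  expect_setequal(r1$tip.label, sub)
  # path lengths preserved
  D <- ape::cophenetic.phylo(tr)[sub, sub]
  expect_equal(ape::cophenetic.phylo(r1)[sub, sub], D, tolerance = 1e-10)
  # restrict twice = restrict to intersection
  r2 <- restrict_tree(r1, sub[1:4])
  r3 <- restrict_tree(tr, sub[1:4])
  expect_setequal(tree_splits(r2), tree_splits(r3))
  # projected bipartitions equal the original's projections
  proj <- function(tree, taxa) {
    keep <- unique(vapply(strsplit(tree_splits(tree), ","), function(s) {
      side <- intersect(s, taxa)
      if (length(side) < 2 || length(side) > length(taxa) - 2) return("")
      ref <- sort(taxa)[1]
      if (ref %in% side) side <- setdiff(taxa, side)
      if (length(side) < 2 || length(side) > length(taxa) - 2) return("")
      paste(sort(side), collapse = ",")
    }, ""))
    setdiff(keep, "")
  }
  expect_setequal(tree_splits(r1), proj(tr, sub))
})

test_that("outgroup rooting places the root on the outgroup stem", {
  tr <- read_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  un <- ape::unroot(tr)
  rooted <- root_with_outgroup(un, c("D", "E"))
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("D", "E")))
  # non-monophyletic outgroup falls back to midpoint with a warning
  expect_warning(root_with_outgroup(un, c("A", "D")), "midpoint")
})
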