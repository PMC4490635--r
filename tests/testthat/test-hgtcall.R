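toy_metadata <- function() {
  data.frame(
    genome_id = c("B1", "B2", "B3", "A1", "A2", "A3", "X1", "X2"),
    kingdom = c(rep("bacteria", 3), rep("archaea", 3), "bacteria",
                "archaea"),
    in_community = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

toy_species <- function() {
  read_newick(paste0("(((B1:1,B2:1):1,(B3:1,X1:1):1):1,",
                     "((A1:1,A2:1):1,(A3:1,X2:1):1):1);"))
}

test_that("low-support incongruence is excluded as a rate artifact", {
  sp <- toy_species()
  # the archaeal subtree is rearranged relative to the species tree, but
  # only on branches with support below the collapse threshold
  gene <- read_newick(paste0("(((B1:1,B2:1)0.95:1,(B3:1,X1:1)0.92:1)0.90:1,",
                             "((A1:1,A3:1)0.55:1,(A2:1,X2:1)0.60:1)0.88:1);"))
  rf <- rate_artifact_filter(gene, sp, support_collapse = 0.70)
  expect_true(rf$exclude)
  # the same incongruence carried by strongly supported branches is kept
  gene2 <- read_newick(paste0("(((B1:1,B2:1)0.95:1,(B3:1,X1:1)0.92:1)0.90:1,",
                              "((A1:1,A3:1)0.98:1,(A2:1,X2:1)0.97:1)0.88:1);"))
  rf2 <- rate_artifact_filter(gene2, sp, support_collapse = 0.70)
  expect_false(rf2$exclude)
  expect_match(rf2$reason, "supported")
})

test_that("a gene tree identical to the species topology is excluded", {
  sp <- toy_species()
  gene <- sp
  gene$node.label <- rep("1.0", gene$Nnode)
  rf <- rate_artifact_filter(gene, sp, 0.70)
  expect_true(rf$exclude)
})

test_that("a misplaced archaeon yields recipients, donor and direction", {
  md <- toy_metadata()
  sp <- toy_species()
  # A1 sits inside the bacterial clade next to (B1,B2): the classic
  # bacteria-to-archaeon transfer signature
  gene <- read_newick(paste0("((((B1:1,B2:1):1,A1:0.5):0.5,(B3:1,X1:1):1):1,",
                             "(A2:1,(A3:1,X2:1):1):1);"))
  call <- infer_transfer(gene, sp, md, family_id = "famT", p_au = 1e-4)
  expect_equal(call$recipients, "A1")
  expect_setequal(call$donor_clade, c("B1", "B2"))
  expect_equal(call$direction, "bacteria->archaea")
  expect_true(call$within_community)
  expect_false(call$complex)
  # removing the recipients restores compatibility (re-checked directly)
  red <- restrict_tree(gene, setdiff(gene$tip.label, call$recipients))
  spr <- restrict_tree(sp, red$tip.label)
  expect_true(all(tree_splits(red) %in% tree_splits(spr)))
})

test_that("a two-leaf recipient pair is recovered with its donor", {
  md <- toy_metadata()
  sp <- toy_species()
  # A2 and A3 together inside the bacteria, sister to (B1,B2)
  gene <- read_newick(paste0("((((B1:1,B2:1):1,(A2:0.5,A3:0.5):0.5):0.5,",
                             "(B3:1,X1:1):1):1,(A1:1,X2:1):1);"))
  call <- infer_transfer(gene, sp, md, family_id = "famP")
  expect_setequal(call$recipients, c("A2", "A3"))
  expect_setequal(call$donor_clade, c("B1", "B2"))
  expect_equal(call$direction, "bacteria->archaea")
})

test_that("direction labels are a pure function of metadata kingdoms", {
  md <- toy_metadata()
  sp <- toy_species()
  gene <- read_newick(paste0("((((B1:1,B2:1):1,A1:0.5):0.5,(B3:1,X1:1):1):1,",
                             "(A2:1,(A3:1,X2:1):1):1);"))
  c1 <- infer_transfer(gene, sp, md, family_id = "f")
  c2 <- infer_transfer(gene, sp, md[sample(nrow(md)), ], family_id = "f")
  expect_identical(c1$direction, c2$direction)
  expect_identical(sort(c1$donor_clade), sort(c2$donor_clade))
})

test_that("a congruent gene tree cannot be called", {
  md <- toy_metadata()
  sp <- toy_species()
  expect_error(infer_transfer(sp, sp, md, family_id = "f"), "compatible")
})

test_that("an irreducible conflict is flagged complex", {
  md <- toy_metadata()
  sp <- toy_species()
  # scrambled tree needing more than 3 removals
  gene <- read_newick(paste0("(((B1:1,A2:1):1,(B2:1,A3:1):1):1,",
                             "((B3:1,X2:1):1,(A1:1,X1:1):1):1);"))
  call <- infer_transfer(gene, sp, md, family_id = "famC", max_remove = 1)
  expect_true(call$complex)
  expect_length(call$recipients, 0)
  expect_true(any(grepl("no removal set", call$audit)))
})

make_call <- function(fid, recipients) {
  structure(list(family_id = fid, recipients = recipients,
                 donor_clade = "B1", direction = "bacteria->archaea",
                 within_community = TRUE, complex = FALSE,
                 p_au = 1e-3, audit = "test"), class = "hgt_call")
}

coord_genome <- function(id, fams, strands, kingdom = "archaea") {
  n <- length(fams)
  starts <- (seq_len(n) - 1L) * 1000L + 1L
  genome_record(id, kingdom, TRUE,
                data.frame(protein_id = fams, residues = strrep("M", 10),
                           contig = "c1", start = starts,
                           end = starts + 599L, strand = strands,
                           stringsAsFactors = FALSE))
}

toy_families <- function(fams, genome = "A1") {
  lapply(fams, function(f) {
    structure(list(family_id = f,
                   members = stats::setNames(f, genome), edges = NULL,
                   n_genomes = 1, n_community = 1),
              class = "ortholog_family")
  })
}

test_that("adjacent same-strand transfers form one cluster", {
  fams <- sprintf("f%02d", 1:9)
  gen <- list(A1 = coord_genome("A1", fams, rep("+", 9)))
  calls <- lapply(fams, make_call, recipients = "A1")
  out <- cluster_transfers(calls, toy_families(fams), gen, cluster_gap = 1)
  ids <- vapply(out, `[[`, "", "cluster_id")
  expect_equal(length(unique(ids)), 1)
  expect_false(any(is.na(ids)))
})

test_that("opposite strands and large gaps split clusters", {
  fams <- sprintf("f%02d", 1:6)
  gen <- list(A1 = coord_genome("A1", fams,
                                c("+", "+", "-", "-", "+", "+")))
  calls <- lapply(fams, make_call, recipients = "A1")
  out <- cluster_transfers(calls, toy_families(fams), gen, cluster_gap = 1)
  ids <- vapply(out, `[[`, "", "cluster_id")
  expect_equal(ids[1], ids[2])
  expect_equal(ids[3], ids[4])
  expect_false(ids[1] == ids[3])
  # gap of 2 genes with cluster_gap 1 separates; with cluster_gap 2 joins
  fams2 <- sprintf("g%02d", 1:5)
  gen2 <- list(A1 = coord_genome("A1", fams2, rep("+", 5)))
  calls2 <- lapply(fams2[c(1, 4)], make_call, recipients = "A1")
  out2 <- cluster_transfers(calls2, toy_families(fams2), gen2,
                            cluster_gap = 1)
  expect_true(all(is.na(vapply(out2, `[[`, "", "cluster_id"))))
  out3 <- cluster_transfers(calls2, toy_families(fams2), gen2,
                            cluster_gap = 2)
  expect_equal(vapply(out3, `[[`, "", "cluster_id")[1],
               vapply(out3, `[[`, "", "cluster_id")[2])
})

test_that("missing coordinates skip clustering with a warning", {
  gen <- list(A1 = toy_genome("A1", c(f01 = "MKLV"), kingdom = "archaea"))
  calls <- list(make_call("f01", "A1"))
  expect_warning(out <- cluster_transfers(calls, toy_families("f01"), gen, 1),
                 "skipped")
  expect_true(is.na(out[[1]]$cluster_id))
})

test_that("summaries report a monotone funnel and direction tallies", {
  funnel <- c(families = 40, au_rejected = 12, rate_survivors = 8,
              calls = 6, within_community = 4)
  calls <- c(lapply(sprintf("f%d", 1:4), make_call, recipients = "A1"),
             list(structure(list(family_id = "f9", recipients = "B1",
                                 donor_clade = "A2",
                                 direction = "archaea->bacteria",
                                 within_community = FALSE, complex = FALSE,
                                 p_au = 0.01, audit = "t"),
                            class = "hgt_call")))
  s <- summarize_calls(funnel, calls)
  expect_true(all(diff(s$funnel) <= 0))
  expect_setequal(s$directions$direction,
                  c("bacteria->archaea", "archaea->bacteria"))
  expect_equal(sum(s$directions$Freq), 5)
  # empty call set still summarizes
  s0 <- summarize_calls(c(families = 0, au_rejected = 0,
                          rate_survivors = 0, calls = 0,
                          within_community = 0), list())
  expect_equal(nrow(s0$directions), 0)
})
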