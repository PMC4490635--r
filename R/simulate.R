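# Forward simulator: two-kingdom species trees, Dayhoff-evolved protein
# families, planted transfer events (single genes and operon-like blocks),
# and rate-shift decoys, with a lossless truth table.

#' Simulation configuration
#'
#' Defaults emulate a small two-kingdom community of the kind studied in
#' acid mine drainage biofilms: 17 genomes (7 bacteria, 10 archaea) of
#' which 8 (2 bacteria + 6 archaea) are community members, 200-site protein
#' families, a maximum tip-to-tip divergence of 1.5 substitutions/site
#' (deep enough for phylogenetic power while cross-kingdom orthologs remain
#' alignable above the 25% identity search threshold), transfers planted
#' between kingdoms inside the community (including operon-like blocks laid
#' out on one strand), and decoy families whose topology matches the
#' organism tree but with 5x rate acceleration on one or two community
#' lineages.
#'
#' @param n_bacteria,n_archaea genomes per kingdom.
#' @param community_bacteria,community_archaea community members per kingdom
#'   (the first genomes of each kingdom).
#' @param n_families total families; every family is present in every
#'   genome.
#' @param n_sites sites (residues) per family.
#' @param tree_height maximum tip-to-tip divergence in substitutions/site.
#' @param n_transfers transferred families (block members included).
#' @param block_sizes sizes of operon-like transferred blocks (each block
#'   shares one donor/recipient event and contiguous same-strand
#'   coordinates); remaining transfers are singletons.
#' @param n_rate_decoys families with lineage rate acceleration only.
#' @param rate_multiplier decoy acceleration factor.
#' @param n_accelerated lineages accelerated per decoy family.
#' @param transfer_depth "recent" grafts onto a donor terminal branch;
#'   "ancient" onto the donor's parent branch.
#' @param seed mandatory simulation seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_bacteria = 7L, n_archaea = 10L,
                       community_bacteria = 2L, community_archaea = 6L,
                       n_families = 60L, n_sites = 200L, tree_height = 1.5,
                       n_transfers = 14L, block_sizes = c(9L, 2L),
                       n_rate_decoys = 10L, rate_multiplier = 5,
                       n_accelerated = 2L,
                       transfer_depth = c("recent", "ancient"), seed) {
  if (missing(seed)) stop("a simulation seed is mandatory")
  transfer_depth <- match.arg(transfer_depth)
  stopifnot(n_bacteria + n_archaea >= 4, n_families >= 1, n_sites >= 1,
            tree_height > 0, n_transfers >= 0, n_rate_decoys >= 0,
            n_transfers + n_rate_decoys <= n_families,
            sum(block_sizes) <= max(n_transfers, 0),
            community_bacteria <= n_bacteria,
            community_archaea <= n_archaea,
            rate_multiplier > 0)
  structure(list(n_bacteria = as.integer(n_bacteria),
                 n_archaea = as.integer(n_archaea),
                 community_bacteria = as.integer(community_bacteria),
                 community_archaea = as.integer(community_archaea),
                 n_families = as.integer(n_families),
                 n_sites = as.integer(n_sites), tree_height = tree_height,
                 n_transfers = as.integer(n_transfers),
                 block_sizes = as.integer(block_sizes),
                 n_rate_decoys = as.integer(n_rate_decoys),
                 rate_multiplier = rate_multiplier,
                 n_accelerated = as.integer(n_accelerated),
                 transfer_depth = transfer_depth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-kingdom ultrametric species tree
#'
#' Bacteria and archaea form the two basal clades; each kingdom clade is a
#' rescaled coalescent tree. Community membership flags are attached as
#' attribute `metadata`.
#'
#' @param config a [sim_config()].
#' @return rooted ultrametric `phylo` with `metadata` attribute
#'   (`genome_id`, `kingdom`, `in_community`).
#' @export
simulate_species_tree <- function(config) {
  set.seed(stage_seed(config$seed, "species_tree"))
  depth_root <- config$tree_height / 2
  depth_clade <- 0.6 * depth_root
  clade <- function(n, prefix) {
    labs <- sprintf("%s%02d", prefix, seq_len(n))
    if (n == 1) {
      return(ape::read.tree(text = sprintf("(%s:%.8g);", labs, depth_clade)))
    }
    tr <- ape::rcoal(n, tip.label = labs)
    d <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth_clade / d
    tr
  }
  bt <- clade(config$n_bacteria, "Bac")
  at <- clade(config$n_archaea, "Arc")
  stem <- depth_root - depth_clade
  nwk <- sprintf("(%s:%.8g,%s:%.8g);",
                 sub(";$", "", write_newick(bt, digits = 10)), stem,
                 sub(";$", "", write_newick(at, digits = 10)), stem)
  tr <- ape::read.tree(text = nwk)
  md <- data.frame(
    genome_id = c(sprintf("Bac%02d", seq_len(config$n_bacteria)),
                  sprintf("Arc%02d", seq_len(config$n_archaea))),
    kingdom = c(rep("bacteria", config$n_bacteria),
                rep("archaea", config$n_archaea)),
    stringsAsFactors = FALSE)
  md$in_community <- c(seq_len(config$n_bacteria) <= config$community_bacteria,
                       seq_len(config$n_archaea) <= config$community_archaea)
  attr(tr, "metadata") <- md
  tr
}

#' Evolve one protein family along a gene genealogy
#'
#' Root sequence drawn from the stationary frequencies; each branch evolves
#' sites independently by sampling from P(branch length).
#'
#' @param tree rooted `phylo` gene genealogy.
#' @param model substitution model.
#' @param n_sites sites.
#' @param seed RNG seed.
#' @return named character vector tip label -> residue string.
#' @export
evolve_family <- function(tree, model = dayhoff_model(), n_sites = 200L,
                          seed = 1L) {
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix(NA_integer_, nnode, n_sites)
  states[root, ] <- sample.int(20, n_sites, replace = TRUE, prob = model$bf)
  # preorder edge traversal
  ord <- order(tree$edge[, 1])
  preorder <- reorder_edges_preorder(tree)
  for (e in preorder) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    P <- prob_matrix(model, tree$edge.length[e])
    ps <- states[par, ]
    cs <- integer(n_sites)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      cs[idx] <- sample.int(20, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[child, ] <- cs
  }
  seqs <- vapply(seq_len(ntip), function(i) {
    paste(model$levels[states[i, ]], collapse = "")
  }, "")
  stats::setNames(seqs, tree$tip.label)
}

reorder_edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  match(paste(tr$edge[, 1], tr$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Plant a transfer event into a gene genealogy
#'
#' Detaches the recipient leaf and regrafts it onto the donor's branch at
#' the given height (time before present, in substitutions/site), so the
#' gene history becomes discordant with the species tree exactly at the
#' recipient. The tree stays ultrametric.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param donor donor leaf label.
#' @param recipient recipient leaf label (distinct from donor).
#' @param attach_height graft height above the present; must lie within the
#'   donor's terminal branch.
#' @return modified `phylo`.
#' @export
plant_transfer <- function(tree, donor, recipient, attach_height) {
  stopifnot(donor %in% tree$tip.label, recipient %in% tree$tip.label,
            donor != recipient)
  tr <- ape::drop.tip(tree, recipient)
  dtip <- match(donor, tr$tip.label)
  dedge <- which(tr$edge[, 2] == dtip)
  if (attach_height <= 0 || attach_height >= tr$edge.length[dedge]) {
    stop("attach_height must lie within the donor's terminal branch (0, ",
         signif(tr$edge.length[dedge], 4), ")")
  }
  graft <- ape::read.tree(text = sprintf("(%s:%.8g);", recipient,
                                         attach_height))
  out <- ape::bind.tree(tr, graft, where = dtip, position = attach_height)
  out
}

# multiply the terminal branch lengths of `leaves` by `factor`
accelerate_lineages <- function(tree, leaves, factor) {
  for (lf in leaves) {
    e <- which(tree$edge[, 2] == match(lf, tree$tip.label))
    tree$edge.length[e] <- tree$edge.length[e] * factor
  }
  tree
}

#' Simulate a full community with planted events and ground truth
#'
#' Builds the species tree, assigns family statuses (null / transfer /
#' rate_decoy), lays transferred blocks out contiguously, evolves every
#' family, and returns genomes, the species tree, coordinates and the
#' truth table. Transfers replace the recipient's native copy, keeping
#' families one-per-genome.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_community`: `genomes` (list of
#'   `genome_record`s with coordinates), `species_tree`, `metadata`,
#'   `truth` (data.frame), `config`.
#' @export
simulate_community <- function(config) {
  model <- dayhoff_model()
  sp <- simulate_species_tree(config)
  md <- attr(sp, "metadata")
  set.seed(stage_seed(config$seed, "layout"))
  layout <- assign_family_slots(config)
  fam_ids <- sprintf("fam%03d", seq_len(config$n_families))
  comm_b <- md$genome_id[md$kingdom == "bacteria" & md$in_community]
  comm_a <- md$genome_id[md$kingdom == "archaea" & md$in_community]
  set.seed(stage_seed(config$seed, "events"))
  events <- plan_events(layout, comm_b, comm_a, sp, config)
  truth <- data.frame(family_id = fam_ids,
                      status = layout$status,
                      donor = NA_character_, recipient = NA_character_,
                      block_id = layout$block_id,
                      attach_height = NA_real_,
                      accelerated = NA_character_,
                      rate_multiplier = NA_real_,
                      strand = layout$strand,
                      stringsAsFactors = FALSE)
  seqs_by_genome <- lapply(md$genome_id, function(g) character(config$n_families))
  names(seqs_by_genome) <- md$genome_id
  for (i in seq_len(config$n_families)) {
    gt <- sp
    st <- layout$status[i]
    if (st == "transfer") {
      ev <- events[[layout$event_of[i]]]
      gt <- plant_transfer(sp, ev$donor, ev$recipient, ev$attach_height)
      truth$donor[i] <- ev$donor
      truth$recipient[i] <- ev$recipient
      truth$attach_height[i] <- ev$attach_height
    } else if (st == "rate_decoy") {
      acc <- sample(c(comm_b, comm_a), config$n_accelerated)
      gt <- accelerate_lineages(sp, acc, config$rate_multiplier)
      truth$accelerated[i] <- paste(acc, collapse = ",")
      truth$rate_multiplier[i] <- config$rate_multiplier
    }
    fam_seqs <- evolve_family(gt, model, config$n_sites,
                              seed = stage_seed(config$seed, "evolve", i))
    for (g in md$genome_id) seqs_by_genome[[g]][i] <- fam_seqs[[g]]
  }
  gene_len <- 3L * config$n_sites
  genomes <- lapply(md$genome_id, function(g) {
    starts <- (seq_len(config$n_families) - 1L) * (gene_len + 400L) + 1L
    genome_record(
      g, md$kingdom[md$genome_id == g], md$in_community[md$genome_id == g],
      data.frame(protein_id = fam_ids, residues = seqs_by_genome[[g]],
                 contig = paste0("ctg_", g), start = starts,
                 end = starts + gene_len - 1L, strand = layout$strand,
                 stringsAsFactors = FALSE),
      source_note = "synthetic community")
  })
  names(genomes) <- md$genome_id
  structure(list(genomes = genomes, species_tree = sp, metadata = md,
                 truth = truth, config = config),
            class = "sim_community")
}

# Family slot allocation: blocks occupy contiguous runs; singleton
# transfers and decoys are kept non-adjacent to other events so clusters
# reflect only the planted blocks. Requires set.seed upstream.
assign_family_slots <- function(config) {
  F <- config$n_families
  status <- rep("null", F)
  block_id <- rep(NA_character_, F)
  event_of <- rep(NA_integer_, F)
  strand <- sample(c("+", "-"), F, replace = TRUE)
  taken <- rep(FALSE, F)      # slot used by an event
  blocked <- rep(FALSE, F)    # slot adjacent to an event
  place_run <- function(len, spaced = TRUE) {
    starts <- sample(seq_len(F - len + 1))
    for (s in starts) {
      span <- s:(s + len - 1)
      # keep two free slots around each event so distinct events never
      # fall within the default clustering gap of each other
      flank <- c(span, s - 2, s - 1, s + len, s + len + 1)
      flank <- flank[flank >= 1 & flank <= F]
      if (!any(taken[span]) &&
          (!spaced || (!any(blocked[span]) && !any(taken[flank])))) {
        return(span)
      }
    }
    if (spaced) return(place_run(len, spaced = FALSE))
    stop("could not place events; too many for n_families")
  }
  ev <- 0L
  for (b in seq_along(config$block_sizes)) {
    span <- place_run(config$block_sizes[b])
    ev <- ev + 1L
    status[span] <- "transfer"
    block_id[span] <- sprintf("B%02d", b)
    event_of[span] <- ev
    strand[span] <- "+"
    taken[span] <- TRUE
    blocked[pmax(span[1] - (1:2), 1)] <- TRUE
    blocked[pmin(span[length(span)] + (1:2), F)] <- TRUE
  }
  n_single <- config$n_transfers - sum(config$block_sizes)
  for (k in seq_len(n_single)) {
    span <- place_run(1L)
    ev <- ev + 1L
    status[span] <- "transfer"
    event_of[span] <- ev
    taken[span] <- TRUE
    blocked[pmax(span - (1:2), 1)] <- TRUE
    blocked[pmin(span + (1:2), F)] <- TRUE
  }
  for (k in seq_len(config$n_rate_decoys)) {
    span <- place_run(1L, spaced = FALSE)
    status[span] <- "rate_decoy"
    taken[span] <- TRUE
  }
  list(status = status, block_id = block_id, event_of = event_of,
       strand = strand)
}

# one donor/recipient/height per event (blocks share one event)
plan_events <- function(layout, comm_b, comm_a, sp, config) {
  if (all(is.na(layout$event_of))) return(list())
  n_events <- max(layout$event_of, na.rm = TRUE)
  lapply(seq_len(n_events), function(e) {
    if (stats::runif(1) < 0.5 && length(comm_b) && length(comm_a)) {
      donor <- sample(comm_b, 1); recipient <- sample(comm_a, 1)
    } else {
      donor <- sample(comm_a, 1); recipient <- sample(comm_b, 1)
    }
    dedge <- sp$edge.length[sp$edge[, 2] == match(donor, sp$tip.label)]
    attach_height <- stats::runif(1, 0.1, 0.6) * dedge
    list(donor = donor, recipient = recipient,
         attach_height = attach_height)
  })
}

#' Write a simulated community to disk
#'
#' Emits per-genome protein FASTA, a metadata TSV, a truth TSV, the species
#' tree (Newick) and per-genome GFF3 gene coordinates, all readable by the
#' package's loaders.
#'
#' @param sim a `sim_community` (or a [sim_config()], which is simulated
#'   first).
#' @param out_dir output directory (created).
#' @return the directory, invisibly.
#' @export
emit_community <- function(sim, out_dir) {
  if (inherits(sim, "sim_config")) sim <- simulate_community(sim)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$config
  md <- sim$metadata
  rows <- lapply(sim$genomes, function(g) {
    fa <- file.path(out_dir, paste0(g$genome_id, ".faa"))
    writeLines(paste0(">", g$proteins$protein_id, "\n", g$proteins$residues),
               fa)
    gff <- file.path(out_dir, paste0(g$genome_id, ".gff3"))
    writeLines(c("##gff-version 3",
                 sprintf("%s\thgtscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         g$proteins$contig, g$proteins$start,
                         g$proteins$end, g$proteins$strand,
                         g$proteins$protein_id)), gff)
    data.frame(genome_id = g$genome_id, kingdom = g$kingdom,
               in_community = g$in_community,
               fasta_path = basename(fa), gff_path = basename(gff),
               stringsAsFactors = FALSE)
  })
  write_tsv_headered(do.call(rbind, rows), file.path(out_dir, "metadata.tsv"),
                     cfg)
  write_tsv_headered(sim$truth, file.path(out_dir, "truth.tsv"), cfg)
  writeLines(write_newick(sim$species_tree),
             file.path(out_dir, "species_tree.nwk"))
  invisible(out_dir)
}
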