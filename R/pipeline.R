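# End-to-end orchestration with resumable per-stage flat-file outputs and
# a JSON run manifest. Stage order follows the detection funnel:
# load -> orthology -> msa -> autest -> ratefilter -> call -> summary.

STAGES <- c("orthology", "msa", "autest", "ratefilter", "call", "summary")

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, manifest_path(out_dir), auto_unbox = TRUE,
                       pretty = TRUE)
}

STAGE_OUTPUTS <- list(
  orthology = c("rbh.tsv", "families.tsv"),
  msa = "msas",
  autest = c("au_report.tsv", "gene_trees.tsv"),
  ratefilter = c("rate_filter.tsv", "consensus_trees.tsv",
                 "gene_trees_collapsed.tsv"),
  call = "calls.tsv",
  summary = "summary.tsv")

# a stage counts as complete only under the same config hash AND with its
# outputs still on disk; a missing intermediate re-runs the stage from its
# predecessors' files
stage_done <- function(manifest, stage, hash, out_dir) {
  !is.null(manifest) && identical(manifest$config_hash, hash) &&
    isTRUE(manifest$stages[[stage]] == "done") &&
    all(file.exists(file.path(out_dir, STAGE_OUTPUTS[[stage]])))
}

mark_stage <- function(out_dir, manifest, stage, hash, seed) {
  if (is.null(manifest) || !identical(manifest$config_hash, hash)) {
    manifest <- list(config_hash = hash, seed = seed,
                     version = as.character(utils::packageVersion("hgtscan")),
                     stage_order = STAGES, stages = list())
  }
  manifest$stages[[stage]] <- "done"
  write_manifest(out_dir, manifest)
  manifest
}

#' Run the full detection pipeline
#'
#' Loads a community (metadata TSV + FASTAs + optional GFF3s and species
#' tree), builds RBH ortholog families, aligns them, applies the AU test
#' against the organism tree, removes rate artifacts, infers transfer
#' calls with clusters, and writes a summary. Each stage writes headered
#' TSV outputs under `out_dir` and is skipped on rerun when the manifest
#' records it as complete under the same configuration.
#'
#' @param input_dir directory containing `metadata.tsv` (and by default
#'   `species_tree.nwk`).
#' @param out_dir results directory (created).
#' @param config an [hgt_config()].
#' @param species_tree_file Newick path; defaults to
#'   `input_dir/species_tree.nwk`.
#' @return list: `summary` (an `hgt_summary`), `calls`, `out_dir`.
#' @export
run_all <- function(input_dir, out_dir, config = hgt_config(),
                    species_tree_file = file.path(input_dir,
                                                  "species_tree.nwk")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  manifest <- read_manifest(out_dir)
  genomes <- load_community(file.path(input_dir, "metadata.tsv"))
  md <- attr(genomes, "metadata")
  sp <- species_tree(species_tree_file, md$genome_id)

  if (!stage_done(manifest, "orthology", hash, out_dir)) {
    stage_orthology(genomes, md, out_dir, config)
    manifest <- mark_stage(out_dir, manifest, "orthology", hash, config$seed)
  } else log_msg("orthology: manifest hit, skipping")

  if (!stage_done(manifest, "msa", hash, out_dir)) {
    stage_msa(genomes, out_dir, config)
    manifest <- mark_stage(out_dir, manifest, "msa", hash, config$seed)
  } else log_msg("msa: manifest hit, skipping")

  if (!stage_done(manifest, "autest", hash, out_dir)) {
    stage_autest(sp, out_dir, config)
    manifest <- mark_stage(out_dir, manifest, "autest", hash, config$seed)
  } else log_msg("autest: manifest hit, skipping")

  if (!stage_done(manifest, "ratefilter", hash, out_dir)) {
    stage_ratefilter(sp, out_dir, config)
    manifest <- mark_stage(out_dir, manifest, "ratefilter", hash, config$seed)
  } else log_msg("ratefilter: manifest hit, skipping")

  if (!stage_done(manifest, "call", hash, out_dir)) {
    stage_call(genomes, md, sp, out_dir, config)
    manifest <- mark_stage(out_dir, manifest, "call", hash, config$seed)
  } else log_msg("call: manifest hit, skipping")

  res <- stage_summary(out_dir, config)
  mark_stage(out_dir, manifest, "summary", hash, config$seed)
  c(res, list(out_dir = out_dir))
}

stage_orthology <- function(genomes, md, out_dir, config) {
  log_msg("orthology: all-vs-all search over %d genomes", length(genomes))
  rbh <- reciprocal_best_hits(genomes, config)
  write_tsv_headered(rbh, file.path(out_dir, "rbh.tsv"), config)
  fams <- annotate_families(build_families(rbh), md)
  write_tsv_headered(families_table(fams),
                     file.path(out_dir, "families_all.tsv"), config)
  kept <- filter_families(fams, config)
  write_tsv_headered(families_table(kept),
                     file.path(out_dir, "families.tsv"), config)
  log_msg("orthology: %d families, %d pass the prevalence filter",
          length(fams), length(kept))
}

read_families <- function(out_dir, genomes) {
  ft <- read_tsv_headered(file.path(out_dir, "families.tsv"))
  lapply(split(ft, ft$family_id), function(df) {
    structure(list(family_id = df$family_id[1],
                   members = stats::setNames(df$protein_id, df$genome_id),
                   edges = NULL, n_genomes = nrow(df),
                   n_community = NA_integer_),
              class = "ortholog_family")
  })
}

stage_msa <- function(genomes, out_dir, config) {
  fams <- read_families(out_dir, genomes)
  dir.create(file.path(out_dir, "msas"), showWarnings = FALSE)
  for (f in fams) {
    seqs <- family_sequences(f, genomes)
    msa <- progressive_align(seqs, gap_open = config$gap_open,
                             gap_extend = config$gap_extend,
                             family_id = f$family_id)
    write_msa_fasta(msa, file.path(out_dir, "msas",
                                   paste0(f$family_id, ".fasta")))
  }
  log_msg("msa: aligned %d families", length(fams))
}

stage_autest <- function(sp, out_dir, config) {
  paths <- sort(list.files(file.path(out_dir, "msas"), full.names = TRUE))
  rows <- list(); trees <- list()
  for (i in seq_along(paths)) {
    fid <- sub("\\.fasta$", "", basename(paths[i]))
    msa <- read_msa_fasta(paths[i], family_id = fid)
    au <- test_family(msa, sp, config,
                      seed = stage_seed(config$seed, "au", i))
    rows[[i]] <- data.frame(
      family_id = fid, n_taxa = length(msa$rows),
      lnl_gene = au$lnl_gene, lnl_species = au$lnl_species,
      d = au$d, c = au$c, p_au = au$p_au, p_bp = au$p_bp,
      degenerate = au$degenerate,
      topologies_identical = au$topologies_identical,
      rejected = au$rejected, stringsAsFactors = FALSE)
    trees[[i]] <- data.frame(family_id = fid,
                             newick = write_newick(au$gene_tree),
                             stringsAsFactors = FALSE)
  }
  write_tsv_headered(do.call(rbind, rows),
                     file.path(out_dir, "au_report.tsv"), config)
  write_tsv_headered(do.call(rbind, trees),
                     file.path(out_dir, "gene_trees.tsv"), config)
  n_rej <- sum(vapply(rows, function(r) r$rejected, TRUE))
  log_msg("autest: %d of %d families reject the organism tree",
          n_rej, length(rows))
}

stage_ratefilter <- function(sp, out_dir, config) {
  au <- read_tsv_headered(file.path(out_dir, "au_report.tsv"))
  rej <- au$family_id[au$rejected]
  rows <- list(); cons_rows <- list(); coll_rows <- list()
  for (i in seq_along(rej)) {
    fid <- rej[i]
    msa <- read_msa_fasta(file.path(out_dir, "msas", paste0(fid, ".fasta")),
                          family_id = fid)
    gt <- read_gene_tree(out_dir, fid)
    bc <- bootstrap_consensus(msa, B = config$bootstrap_reps,
                              seed = stage_seed(config$seed, "boot",
                                                match(fid, au$family_id)),
                              start_tree = gt)
    rf <- rate_artifact_filter(bc$consensus, sp, config$support_collapse)
    rows[[i]] <- data.frame(family_id = fid, exclude = rf$exclude,
                            reason = rf$reason, stringsAsFactors = FALSE)
    cons_rows[[i]] <- data.frame(family_id = fid,
                                 newick = write_newick(bc$consensus),
                                 stringsAsFactors = FALSE)
    # the ML gene tree with unsupported edges collapsed: recipient
    # inference later reads only well-supported conflicts
    coll <- collapse_unsupported(gt, split_frequencies(bc$trees),
                                 config$support_collapse)
    coll_rows[[i]] <- data.frame(family_id = fid,
                                 newick = write_newick(coll),
                                 stringsAsFactors = FALSE)
  }
  empty <- data.frame(family_id = character(0), exclude = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  write_tsv_headered(if (length(rows)) do.call(rbind, rows) else empty,
                     file.path(out_dir, "rate_filter.tsv"), config)
  empty_tr <- data.frame(family_id = character(0), newick = character(0))
  write_tsv_headered(if (length(cons_rows)) do.call(rbind, cons_rows) else
                       empty_tr,
                     file.path(out_dir, "consensus_trees.tsv"), config)
  write_tsv_headered(if (length(coll_rows)) do.call(rbind, coll_rows) else
                       empty_tr,
                     file.path(out_dir, "gene_trees_collapsed.tsv"), config)
  if (length(rows)) {
    log_msg("ratefilter: excluded %d of %d rejected families as artifacts",
            sum(vapply(rows, function(r) r$exclude, TRUE)), length(rows))
  }
}

read_gene_tree <- function(out_dir, fid) {
  gt <- read_tsv_headered(file.path(out_dir, "gene_trees.tsv"))
  read_newick(gt$newick[match(fid, gt$family_id)])
}

stage_call <- function(genomes, md, sp, out_dir, config) {
  au <- read_tsv_headered(file.path(out_dir, "au_report.tsv"))
  rf <- read_tsv_headered(file.path(out_dir, "rate_filter.tsv"))
  surv <- intersect(au$family_id[au$p_au < config$alpha],
                    rf$family_id[!rf$exclude])
  fams <- read_families(out_dir, genomes)
  coll <- read_tsv_headered(file.path(out_dir, "gene_trees_collapsed.tsv"))
  calls <- list()
  for (fid in sort(surv)) {
    gt <- if (fid %in% coll$family_id) {
      read_newick(coll$newick[match(fid, coll$family_id)])
    } else {
      read_gene_tree(out_dir, fid)
    }
    rooted <- root_gene_tree(gt, fams[[fid]], config)
    cl <- tryCatch(
      infer_transfer(rooted, sp, md, family_id = fid,
                     p_au = au$p_au[match(fid, au$family_id)]),
      error = function(e) NULL)
    if (!is.null(cl)) calls[[length(calls) + 1L]] <- cl
  }
  calls <- cluster_transfers(calls, fams, genomes, config$cluster_gap)
  write_tsv_headered(calls_table(calls), file.path(out_dir, "calls.tsv"),
                     config)
  log_msg("call: %d transfer calls (%d within-community)", length(calls),
          sum(vapply(calls, `[[`, TRUE, "within_community")))
}

# Gene trees are rooted with the configured conserved outgroup family's
# taxa when such leaves are present (interoperability path); otherwise by
# midpoint, which suits the one-gene-per-genome trees the pipeline builds.
root_gene_tree <- function(tree, family, config) {
  og <- grep(paste0("^", config$outgroup_family), tree$tip.label,
             value = TRUE)
  if (length(og) && length(og) < length(tree$tip.label)) {
    suppressWarnings(root_with_outgroup(tree, og))
  } else {
    phangorn::midpoint(tree)
  }
}

stage_summary <- function(out_dir, config) {
  au <- read_tsv_headered(file.path(out_dir, "au_report.tsv"))
  rf <- read_tsv_headered(file.path(out_dir, "rate_filter.tsv"))
  ct <- read_tsv_headered(file.path(out_dir, "calls.tsv"))
  calls <- lapply(seq_len(nrow(ct)), function(i) {
    structure(list(family_id = ct$family_id[i],
                   recipients = strsplit(ct$recipients[i], ",")[[1]],
                   donor_clade = strsplit(ct$donor_clade[i], ",")[[1]],
                   direction = ct$direction[i],
                   within_community = ct$within_community[i],
                   complex = ct$complex[i],
                   cluster_id = ct$cluster_id[i], p_au = ct$p_au[i],
                   audit = ct$audit[i]), class = "hgt_call")
  })
  good <- ct[!ct$complex & nzchar(ct$recipients), , drop = FALSE]
  funnel <- c(families = nrow(au),
              au_rejected = sum(au$rejected),
              rate_survivors = sum(!rf$exclude),
              calls = nrow(good),
              within_community = sum(good$within_community))
  summ <- summarize_calls(funnel, calls)
  write_tsv_headered(data.frame(stage = names(funnel),
                                count = as.integer(funnel)),
                     file.path(out_dir, "summary.tsv"), config)
  txt <- utils::capture.output(print(summ))
  writeLines(c(sprintf("# hgtscan config=%s seed=%d",
                       config_hash(unclass(config)), config$seed), txt),
             file.path(out_dir, "summary.txt"))
  list(summary = summ, calls = calls)
}

#' Evaluate a run against a simulation truth table
#'
#' @param out_dir results directory of [run_all()].
#' @param truth truth data.frame from [simulate_community()] (or the
#'   emitted `truth.tsv`).
#' @return list with sensitivity, recipient accuracy, decoy handling and
#'   cluster agreement measures.
#' @export
evaluate_against_truth <- function(out_dir, truth) {
  if (is.character(truth)) truth <- read_tsv_headered(truth)
  au <- read_tsv_headered(file.path(out_dir, "au_report.tsv"))
  rf <- read_tsv_headered(file.path(out_dir, "rate_filter.tsv"))
  ct <- read_tsv_headered(file.path(out_dir, "calls.tsv"))
  ft <- read_tsv_headered(file.path(out_dir, "families.tsv"))
  # detected family ids differ from simulated ones; simulated proteins are
  # named after their family, so a detected family maps to the majority
  # protein id of its members
  sim_of <- vapply(split(ft$protein_id, ft$family_id), function(p) {
    names(sort(table(p), decreasing = TRUE))[1]
  }, "")
  good <- ct[!ct$complex & nzchar(ct$recipients), , drop = FALSE]
  good$sim <- unname(sim_of[good$family_id])
  transfers <- truth$family_id[truth$status == "transfer"]
  decoys <- truth$family_id[truth$status == "rate_decoy"]
  sens <- if (length(transfers)) mean(transfers %in% good$sim) else NA_real_
  called_tr <- good[good$sim %in% transfers, , drop = FALSE]
  rec_ok <- vapply(seq_len(nrow(called_tr)), function(i) {
    want <- truth$recipient[truth$family_id == called_tr$sim[i]]
    setequal(strsplit(called_tr$recipients[i], ",")[[1]], want)
  }, TRUE)
  rej_decoys <- intersect(decoys, sim_of[au$family_id[au$rejected]])
  removed <- intersect(rej_decoys, sim_of[rf$family_id[rf$exclude]])
  # block agreement: called members of each planted block must share one
  # cluster id that no call outside the block carries
  blocks <- unique(stats::na.omit(truth$block_id))
  block_ok <- vapply(blocks, function(b) {
    fams_b <- truth$family_id[!is.na(truth$block_id) & truth$block_id == b]
    cl_in <- good$cluster_id[good$sim %in% fams_b]
    cl_out <- good$cluster_id[!good$sim %in% fams_b]
    if (length(cl_in) < 2) return(NA)
    length(unique(cl_in)) == 1 && !any(is.na(cl_in)) &&
      !cl_in[1] %in% cl_out
  }, NA)
  list(sensitivity = sens,
       recipient_accuracy = if (nrow(called_tr)) mean(rec_ok) else NA_real_,
       decoys_rejected = length(rej_decoys),
       decoys_removed = length(removed),
       decoy_removal_rate = if (length(rej_decoys))
         length(removed) / length(rej_decoys) else NA_real_,
       false_calls = sum(!good$sim %in% transfers),
       n_calls = nrow(good),
       blocks_clustered = block_ok)
}
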