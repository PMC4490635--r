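# From AU rejections to transfer calls: rate-artifact exclusion,
# donor/recipient/direction inference, within-community refinement, and
# transferred-cluster (operon-like) detection.

# all non-trivial splits of `tree` occur in `ref` (same leaf set)
splits_compatible <- function(tree_splits_chr, ref_splits_chr) {
  all(tree_splits_chr %in% ref_splits_chr)
}

#' Rate-artifact exclusion filter
#'
#' Collapses gene-consensus-tree branches with bootstrap support below
#' `support_collapse`; if the collapsed tree is compatible with the species
#' topology (every remaining bipartition occurs in it), the family's
#' incongruence is attributed to rate/resolution artifacts and the family
#' is excluded.
#'
#' @param gene_consensus `phylo` with numeric node labels (supports in
#'   [0, 1]).
#' @param species_topology `phylo` over the same taxa.
#' @param support_collapse collapse threshold.
#' @return list: `exclude` (logical), `kept_splits`, `reason`.
#' @export
rate_artifact_filter <- function(gene_consensus, species_topology,
                                 support_collapse = 0.70) {
  gs <- supported_splits(gene_consensus, support_collapse)
  ss <- tree_splits(restrict_tree(species_topology,
                                  gene_consensus$tip.label))
  compat <- splits_compatible(gs, ss)
  list(exclude = compat, kept_splits = gs,
       reason = if (compat) "collapsed tree compatible with organism tree"
                else "supported incongruence")
}

# splits of a tree whose support label passes the threshold; unlabeled
# splits are treated as fully supported
supported_splits <- function(tree, threshold) {
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  ref <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  out <- character(0)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) next
    s <- if (length(sup) >= i) sup[i] else NA_real_
    if (!is.na(s) && s < threshold) next
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

#' Infer recipients, donor clade and direction for one incongruent family
#'
#' Searches greedily for the minimal leaf set (singletons, then pairs, then
#' triples; lexicographic order) whose removal makes the gene tree
#' compatible with the species topology. The donor clade is the recipients'
#' sister group in the rooted gene tree; direction is read from kingdom
#' labels (donor-clade majority kingdom to recipient kingdom).
#'
#' @param gene_tree_rooted rooted gene tree (`phylo`).
#' @param species rooted organism tree (superset of the family's taxa).
#' @param metadata data.frame with `genome_id`, `kingdom`, `in_community`.
#' @param family_id label carried into the call.
#' @param p_au AU p-value carried into the call.
#' @param max_remove largest removal set searched.
#' @return object of class `hgt_call`: `family_id`, `recipients`,
#'   `donor_clade`, `direction`, `within_community`, `complex`, `audit`.
#' @export
infer_transfer <- function(gene_tree_rooted, species, metadata,
                           family_id = NA_character_, p_au = NA_real_,
                           max_remove = 3L) {
  taxa <- gene_tree_rooted$tip.label
  sp <- restrict_tree(species, taxa)
  audit <- character(0)
  gsplits_all <- tree_splits(gene_tree_rooted)
  if (splits_compatible(gsplits_all, tree_splits(sp))) {
    stop("gene tree is compatible with the species topology; nothing to call")
  }
  # minimal removal sets are not always unique (removing either side of a
  # displaced cherry can restore compatibility), so all candidates of the
  # smallest working size are scored by displacement: the true recipients
  # sit maximally far (topologically, in the species tree) from their
  # gene-tree sister group
  topo_dist <- topo_distances(sp)
  recipients <- NULL
  for (size in seq_len(max(min(max_remove, length(taxa) - 4L), 0L))) {
    hits <- list()
    for (S in utils::combn(sort(taxa), size, simplify = FALSE)) {
      keep <- setdiff(taxa, S)
      g2 <- restrict_tree(gene_tree_rooted, keep)
      s2 <- restrict_tree(sp, keep)
      if (splits_compatible(tree_splits(g2), tree_splits(s2))) {
        hits[[length(hits) + 1L]] <- S
      }
    }
    if (length(hits)) {
      score <- vapply(hits, function(S) {
        D <- donor_clade_of(gene_tree_rooted, S)
        mean(topo_dist[S, D, drop = FALSE])
      }, 0)
      recipients <- hits[[order(-score, vapply(hits, paste, "",
                                               collapse = ","))[1]]]
      break
    }
  }
  if (is.null(recipients)) {
    audit <- c(audit, sprintf("no removal set of size <= %d restores compatibility",
                              max_remove))
    return(structure(list(family_id = family_id, recipients = character(0),
                          donor_clade = character(0),
                          direction = NA_character_,
                          within_community = FALSE, complex = TRUE,
                          p_au = p_au, audit = audit), class = "hgt_call"))
  }
  audit <- c(audit, sprintf("recipients {%s} restore compatibility",
                            paste(recipients, collapse = ",")))
  donor <- donor_clade_of(gene_tree_rooted, recipients)
  kingdom_of <- stats::setNames(metadata$kingdom, metadata$genome_id)
  comm <- stats::setNames(metadata$in_community, metadata$genome_id)
  donor_k <- majority(kingdom_of[donor])
  recip_k <- majority(kingdom_of[recipients])
  direction <- if (identical(donor_k, recip_k)) "within-kingdom"
               else paste0(donor_k, "->", recip_k)
  within <- all(comm[recipients]) && any(comm[donor])
  audit <- c(audit, sprintf("donor clade {%s}; direction %s",
                            paste(donor, collapse = ","), direction))
  structure(list(family_id = family_id, recipients = recipients,
                 donor_clade = donor, direction = direction,
                 within_community = within, complex = FALSE,
                 p_au = p_au, audit = audit), class = "hgt_call")
}

# pairwise topological (unit-edge) leaf distances
topo_distances <- function(tree) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  ape::cophenetic.phylo(tr)
}

majority <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

# leaf set of the recipients' sister group in the rooted gene tree
donor_clade_of <- function(tree, recipients) {
  tips_of <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  if (length(recipients) == 1) {
    node <- match(recipients, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, recipients)
  }
  clade <- tips_of(node)
  if (!setequal(clade, recipients)) {
    # recipients not exactly monophyletic: use the rest of their clade
    return(setdiff(clade, recipients))
  }
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (!length(parent)) return(setdiff(tree$tip.label, recipients))
  setdiff(tips_of(parent), recipients)
}

#' @export
print.hgt_call <- function(x, ...) {
  cat(sprintf("<hgt_call> %s: %s -> {%s}%s\n", x$family_id %||% "?",
              x$direction %||% "?", paste(x$recipients, collapse = ","),
              if (x$within_community) " [within-community]" else ""))
  invisible(x)
}

#' Group transfer calls into gene clusters (operon-like blocks)
#'
#' Two calls share a cluster iff they have a common recipient genome, their
#' recipient genes lie on the same contig and strand, and at most
#' `cluster_gap` genes intervene. Calls without coordinates are left
#' unclustered (with a warning).
#'
#' @param calls list of `hgt_call`s.
#' @param families family list (maps family to each genome's protein).
#' @param genomes named list of `genome_record`s carrying coordinates.
#' @param cluster_gap max intervening genes.
#' @return the calls, each with a `cluster_id` field (NA when unclustered).
#' @export
cluster_transfers <- function(calls, families, genomes, cluster_gap = 1L) {
  if (!length(calls)) return(calls)
  fam_by_id <- stats::setNames(families, vapply(families, `[[`, "", "family_id"))
  have_coords <- any(vapply(genomes, function(g) "start" %in% names(g$proteins) &&
                              any(!is.na(g$proteins$start)), TRUE))
  if (!have_coords) {
    warning("no gene coordinates available; cluster detection skipped")
    for (i in seq_along(calls)) calls[[i]]$cluster_id <- NA_character_
    return(calls)
  }
  # gene rank per (genome, contig) by start coordinate
  recs <- list()
  for (i in seq_along(calls)) {
    cl <- calls[[i]]
    calls[[i]]$cluster_id <- NA_character_
    if (cl$complex || !length(cl$recipients)) next
    fam <- fam_by_id[[cl$family_id]]
    for (g in intersect(cl$recipients, names(genomes))) {
      pid <- fam$members[[g]]
      pr <- genomes[[g]]$proteins
      j <- match(pid, pr$protein_id)
      if (is.na(j) || is.na(pr$start[j])) next
      ord <- order(pr$start[pr$contig == pr$contig[j]])
      rank <- match(j, which(pr$contig == pr$contig[j])[ord])
      recs[[length(recs) + 1L]] <- data.frame(
        call = i, genome = g, contig = pr$contig[j], strand = pr$strand[j],
        rank = rank, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(calls)
  rd <- do.call(rbind, recs)
  cid <- 0L
  for (key in unique(paste(rd$genome, rd$contig, rd$strand))) {
    sub <- rd[paste(rd$genome, rd$contig, rd$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    if (nrow(sub) < 2) next
    grp <- cumsum(c(1, diff(sub$rank) - 1 > cluster_gap))
    for (gid in unique(grp)) {
      members <- sub$call[grp == gid]
      if (length(members) < 2) next
      cid <- cid + 1L
      for (m in members) calls[[m]]$cluster_id <- sprintf("C%03d", cid)
    }
  }
  calls
}

#' Summarize a detection run
#'
#' Funnel counts per stage, direction tallies, cluster memberships, and an
#' optional functional-category tally when a gene-to-category map is given.
#'
#' @param funnel named integer vector of stage counts (families, au_rejected,
#'   rate_survivors, calls, within_community).
#' @param calls list of `hgt_call`s.
#' @param category_map optional data.frame (`family_id`, `category`).
#' @return list of class `hgt_summary` with `funnel`, `directions`,
#'   `clusters`, `categories`.
#' @export
summarize_calls <- function(funnel, calls, category_map = NULL) {
  ok <- Filter(function(x) !x$complex && length(x$recipients), calls)
  directions <- if (length(ok)) {
    as.data.frame(table(direction = vapply(ok, `[[`, "", "direction")),
                  stringsAsFactors = FALSE)
  } else data.frame(direction = character(0), Freq = integer(0))
  cl <- vapply(calls, function(x) as.character(x$cluster_id %||% NA), "")
  clusters <- if (any(!is.na(cl))) {
    data.frame(cluster_id = cl[!is.na(cl)],
               family_id = vapply(calls[!is.na(cl)], `[[`, "", "family_id"),
               stringsAsFactors = FALSE)
  } else data.frame(cluster_id = character(0), family_id = character(0))
  categories <- NULL
  if (!is.null(category_map) && length(ok)) {
    fams <- vapply(ok, `[[`, "", "family_id")
    m <- category_map[category_map$family_id %in% fams, , drop = FALSE]
    categories <- as.data.frame(table(category = m$category),
                                stringsAsFactors = FALSE)
  }
  structure(list(funnel = funnel, directions = directions,
                 clusters = clusters, categories = categories),
            class = "hgt_summary")
}

#' @export
print.hgt_summary <- function(x, ...) {
  cat("HGT detection summary\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-18s %d\n", nm, x$funnel[[nm]]))
  if (nrow(x$directions)) {
    cat("Directions:\n")
    for (i in seq_len(nrow(x$directions))) {
      cat(sprintf("  %-24s %d\n", x$directions$direction[i],
                  x$directions$Freq[i]))
    }
  }
  if (nrow(x$clusters)) {
    cat(sprintf("Clusters: %d (families: %s)\n",
                length(unique(x$clusters$cluster_id)),
                paste(x$clusters$family_id, collapse = ",")))
  }
  invisible(x)
}

#' Calls as a data.frame
#' @param calls list of `hgt_call`s.
#' @export
calls_table <- function(calls) {
  if (!length(calls)) {
    return(data.frame(family_id = character(0), recipients = character(0),
                      donor_clade = character(0), direction = character(0),
                      within_community = logical(0), complex = logical(0),
                      cluster_id = character(0), p_au = numeric(0),
                      audit = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(calls, function(x) {
    data.frame(family_id = x$family_id,
               recipients = paste(x$recipients, collapse = ","),
               donor_clade = paste(x$donor_clade, collapse = ","),
               direction = x$direction %||% NA_character_,
               within_community = x$within_community,
               complex = x$complex,
               cluster_id = x$cluster_id %||% NA_character_,
               p_au = x$p_au,
               audit = paste(x$audit, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}
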