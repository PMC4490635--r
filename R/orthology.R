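# Strict reciprocal-best-hit orthology: all-vs-all search, RBH graph,
# family construction (connected components, split to one-per-genome) and
# the prevalence filter.

#' Strict reciprocal best hits between all genome pairs
#'
#' For every ordered pair of distinct genomes each protein's best hit is the
#' subject with the unique highest bit score; a pair is an RBH edge iff the
#' two best-hit relations are mutual and the alignment passes
#' `evalue <= evalue_max`, `identity > identity_min` and
#' `aln_cols / shorter length > coverage_min` (strict inequalities on
#' identity and coverage). Bit-score ties mean no unique best hit and the
#' protein contributes no edge ("strict" RBH).
#'
#' @param genomes named list of `genome_record`s (>= 2).
#' @param config an [hgt_config()].
#' @return data.frame of RBH edges: `genome_a`, `protein_a`, `genome_b`,
#'   `protein_b` plus alignment statistics.
#' @export
reciprocal_best_hits <- function(genomes, config = hgt_config()) {
  if (length(genomes) < 2) stop("need at least 2 genomes")
  ids <- names(genomes)
  enc <- lapply(genomes, function(g) lapply(g$proteins$residues, encode_residues))
  lens <- lapply(genomes, function(g) nchar(g$proteins$residues))
  sub <- blosum62_matrix()
  out <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1), length(ids))) {
      sm <- cpp_sw_score_matrix(enc[[i]], enc[[j]], sub,
                                config$gap_open, config$gap_extend)
      # unique argmax per row (i -> j) and per column (j -> i)
      best_j <- unique_argmax_rows(sm)
      best_i <- unique_argmax_rows(t(sm))
      cand <- which(!is.na(best_j))
      for (p in cand) {
        q <- best_j[p]
        if (is.na(best_i[q]) || best_i[q] != p) next
        if (sm[p, q] <= 0) next
        hit <- local_align(genomes[[i]]$proteins$residues[p],
                           genomes[[j]]$proteins$residues[q],
                           query_id = genomes[[i]]$proteins$protein_id[p],
                           subject_id = genomes[[j]]$proteins$protein_id[q],
                           gap_open = config$gap_open,
                           gap_extend = config$gap_extend)
        if (is.null(hit)) next
        if (hit$evalue > config$evalue_max) next
        if (hit$identity <= config$identity_min) next
        if (hit$cover_short <= config$coverage_min) next
        out[[length(out) + 1L]] <- data.frame(
          genome_a = ids[i], protein_a = hit$query_id,
          genome_b = ids[j], protein_b = hit$subject_id,
          raw_score = hit$raw_score, bit_score = hit$bit_score,
          evalue = hit$evalue, identity = hit$identity,
          aln_cols = hit$aln_cols, q_cover = hit$q_cover,
          s_cover = hit$s_cover, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(genome_a = character(), protein_a = character(),
                      genome_b = character(), protein_b = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), identity = numeric(),
                      aln_cols = integer(), q_cover = numeric(),
                      s_cover = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# index of the strictly unique maximum of each row, NA when tied or all <= 0
unique_argmax_rows <- function(m) {
  apply(m, 1, function(r) {
    mx <- max(r)
    if (mx <= 0) return(NA_integer_)
    w <- which(r == mx)
    if (length(w) != 1L) NA_integer_ else w
  })
}

#' Build ortholog families from RBH edges
#'
#' Families are connected components of the RBH graph. A component holding
#' two proteins of one genome is split by repeatedly deleting its
#' lowest-bit-score edge (ties broken by lexicographic edge label) until
#' every component is one-per-genome. Single proteins left without edges are
#' dropped. Family ids are assigned deterministically by sorted membership.
#'
#' @param rbh data.frame from [reciprocal_best_hits()].
#' @return list of `ortholog_family` objects (fields `family_id`, `members`
#'   named genome -> protein, `edges`, `n_genomes`, `n_community`).
#' @export
build_families <- function(rbh) {
  if (nrow(rbh) == 0) return(list())
  node <- function(g, p) paste0(g, "|", p)
  va <- node(rbh$genome_a, rbh$protein_a)
  vb <- node(rbh$genome_b, rbh$protein_b)
  edge_key <- paste(pmin(va, vb), pmax(va, vb))
  g <- igraph::graph_from_data_frame(
    data.frame(from = va, to = vb, weight = rbh$bit_score, key = edge_key,
               row = seq_len(nrow(rbh)), stringsAsFactors = FALSE),
    directed = FALSE)
  genome_of <- function(gr) sub("\\|.*$", "", igraph::V(gr)$name)
  repeat {
    comp <- igraph::components(g)
    gmv <- genome_of(g)
    bad <- NULL
    for (cid in seq_len(comp$no)) {
      vs <- which(comp$membership == cid)
      if (anyDuplicated(gmv[vs])) { bad <- cid; break }
    }
    if (is.null(bad)) break
    vs <- which(comp$membership == bad)
    eids <- unique(unlist(igraph::incident_edges(g, vs)))
    w <- igraph::edge_attr(g, "weight", eids)
    k <- igraph::edge_attr(g, "key", eids)
    ord <- order(w, k)   # lowest bit score first, then lexicographic label
    g <- igraph::delete_edges(g, eids[ord[1]])
  }
  comp <- igraph::components(g)
  edf <- igraph::as_data_frame(g, what = "edges")
  ecomp <- comp$membership[edf$from]
  fams <- list()
  for (cid in seq_len(comp$no)) {
    vs <- igraph::V(g)$name[comp$membership == cid]
    if (length(vs) < 2) next
    gm <- sub("\\|.*$", "", vs)
    pr <- sub("^[^|]*\\|", "", vs)
    o <- order(gm)
    members <- stats::setNames(pr[o], gm[o])
    fams[[length(fams) + 1L]] <-
      list(members = members, edges = rbh[edf$row[ecomp == cid], , drop = FALSE])
  }
  # deterministic ids by sorted membership signature
  sig <- vapply(fams, function(f) paste(names(f$members), f$members,
                                        collapse = ";"), "")
  fams <- fams[order(sig)]
  lapply(seq_along(fams), function(i) {
    f <- fams[[i]]
    structure(list(family_id = sprintf("F%04d", i), members = f$members,
                   edges = f$edges, n_genomes = length(f$members),
                   n_community = NA_integer_),
              class = "ortholog_family")
  })
}

#' @export
print.ortholog_family <- function(x, ...) {
  cat(sprintf("<ortholog_family> %s: %d genomes\n", x$family_id, x$n_genomes))
  invisible(x)
}

#' Annotate families with community membership counts
#' @param families list from [build_families()].
#' @param metadata data.frame with `genome_id` and `in_community`.
#' @export
annotate_families <- function(families, metadata) {
  comm <- metadata$genome_id[metadata$in_community]
  lapply(families, function(f) {
    f$n_community <- sum(names(f$members) %in% comm)
    f
  })
}

#' Prevalence filter for ortholog families
#'
#' Keeps families present in at least `min_genomes` genomes (the "more than
#' seven genomes" rule at the default of 8) with at least `min_community`
#' community members.
#'
#' @param families annotated family list.
#' @param config an [hgt_config()].
#' @export
filter_families <- function(families, config = hgt_config()) {
  Filter(function(f) f$n_genomes >= config$min_genomes &&
           !is.na(f$n_community) && f$n_community >= config$min_community,
         families)
}

#' Family list as a long data.frame (family_id, genome_id, protein_id)
#' @param families family list.
#' @export
families_table <- function(families) {
  if (!length(families)) {
    return(data.frame(family_id = character(), genome_id = character(),
                      protein_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(families, function(f) {
    data.frame(family_id = f$family_id, genome_id = names(f$members),
               protein_id = unname(f$members), stringsAsFactors = FALSE)
  }))
}

#' Extract a family's sequences from the genomes
#' @param family an `ortholog_family`.
#' @param genomes named list of `genome_record`s.
#' @return named character vector genome_id -> residues.
#' @export
family_sequences <- function(family, genomes) {
  vapply(names(family$members), function(g) {
    p <- family$members[[g]]
    i <- match(p, genomes[[g]]$proteins$protein_id)
    if (is.na(i)) stop("protein ", p, " not found in genome ", g)
    genomes[[g]]$proteins$residues[i]
  }, "")
}
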