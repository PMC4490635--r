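# Domain types and file IO: genome records, metadata tables, Newick
# round-tripping, run configuration.

#' Run configuration
#'
#' Thresholds and tuning parameters for a detection run. Defaults follow the
#' strict reciprocal-best-hit criteria (E-value cutoff 1e-5, identity > 25%,
#' alignment length > 60% of the shorter sequence), the family prevalence
#' rule (present in at least `min_genomes` genomes with at least one
#' community member), 100 bootstrap replicates with majority-rule consensus,
#' and the AU-test significance level 0.05.
#'
#' @param evalue_max maximum E-value for an accepted hit.
#' @param identity_min identity fraction; hits must exceed this (strict).
#' @param coverage_min alignment columns / length of the shorter sequence;
#'   hits must exceed this (strict).
#' @param min_genomes minimum number of genomes per retained family.
#' @param min_community minimum community members per retained family.
#' @param alpha AU-test rejection level.
#' @param bootstrap_reps bootstrap replicates for the consensus tree.
#' @param rell_B RELL resamples per scale.
#' @param scales multiscale bootstrap scales (relative resample sizes).
#' @param support_collapse gene-tree branches with bootstrap support below
#'   this are collapsed before the rate-artifact compatibility check.
#' @param cluster_gap maximum number of intervening genes between two
#'   transferred genes grouped into one cluster.
#' @param outgroup_family name of a conserved family used to root gene trees
#'   when present (e.g. radA); midpoint rooting otherwise.
#' @param gap_open,gap_extend affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param seed run seed; all stage RNG streams derive from it.
#' @return list of class `hgt_config`.
#' @export
hgt_config <- function(evalue_max = 1e-5, identity_min = 0.25,
                       coverage_min = 0.60, min_genomes = 8L,
                       min_community = 1L, alpha = 0.05,
                       bootstrap_reps = 100L, rell_B = 1000L,
                       scales = seq(0.5, 1.4, by = 0.1),
                       support_collapse = 0.70, cluster_gap = 1L,
                       outgroup_family = "radA",
                       gap_open = 11L, gap_extend = 1L, seed = 1L) {
  stopifnot(evalue_max > 0, identity_min >= 0, identity_min <= 1,
            coverage_min >= 0, coverage_min <= 1, min_genomes >= 2,
            alpha > 0, alpha < 1, bootstrap_reps >= 1, rell_B >= 100,
            all(scales > 0), support_collapse >= 0, support_collapse <= 1,
            cluster_gap >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 coverage_min = coverage_min, min_genomes = as.integer(min_genomes),
                 min_community = as.integer(min_community), alpha = alpha,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 rell_B = as.integer(rell_B), scales = scales,
                 support_collapse = support_collapse,
                 cluster_gap = as.integer(cluster_gap),
                 outgroup_family = outgroup_family,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed = as.integer(seed)),
            class = "hgt_config")
}

#' Read a protein FASTA file into a genome record
#'
#' @param path FASTA file of protein sequences.
#' @param genome_id short unique genome label.
#' @param kingdom "bacteria" or "archaea".
#' @param in_community logical; is this genome a community member?
#' @return object of class `genome_record`: fields `genome_id`, `kingdom`,
#'   `in_community` and `proteins` (data.frame with `protein_id`,
#'   `residues`, optional coordinates).
#' @export
read_protein_fasta <- function(path, genome_id, kingdom = NA_character_,
                               in_community = NA) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(aa) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- normalize_residues(as.character(aa))
  if (any(nchar(res) < 1)) stop("zero-length sequence in ", path)
  genome_record(genome_id, kingdom, in_community,
                data.frame(protein_id = ids, residues = unname(res),
                           stringsAsFactors = FALSE))
}

#' Construct a genome record
#' @param genome_id genome label.
#' @param kingdom "bacteria" or "archaea" (NA allowed until metadata joins).
#' @param in_community logical flag.
#' @param proteins data.frame with columns `protein_id`, `residues` and
#'   optionally `contig`, `start`, `end`, `strand` (1-based inclusive).
#' @param source_note free-text provenance.
#' @export
genome_record <- function(genome_id, kingdom, in_community, proteins,
                          source_note = "") {
  if (!is.na(kingdom) && !kingdom %in% c("bacteria", "archaea")) {
    stop("unknown kingdom '", kingdom, "' (must be bacteria or archaea)")
  }
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "residues") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id)) stop("duplicate protein ids")
  if (all(c("start", "end", "strand") %in% names(proteins))) {
    ok <- is.na(proteins$start) |
      (proteins$start <= proteins$end & proteins$strand %in% c("+", "-"))
    if (!all(ok)) stop("invalid coordinates (need start <= end, strand +/-)")
  }
  structure(list(genome_id = genome_id, kingdom = kingdom,
                 in_community = in_community, proteins = proteins,
                 source_note = source_note),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s [%s%s] %d proteins\n", x$genome_id,
              x$kingdom, if (isTRUE(x$in_community)) ", community" else "",
              nrow(x$proteins)))
  invisible(x)
}

#' Read a genome metadata table
#'
#' TSV with header columns `genome_id`, `kingdom`, `in_community`,
#' `fasta_path` and optionally `gff_path`. Kingdom strings are matched
#' case-insensitively against bacteria/archaea.
#'
#' @param path TSV path.
#' @return data.frame of validated genome descriptors; genome labels are
#'   sanitized for Newick safety and the original names kept in
#'   `original_id`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("genome_id", "kingdom", "in_community", "fasta_path")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  k <- tolower(trimws(md$kingdom))
  bad <- !k %in% c("bacteria", "archaea")
  if (any(bad)) stop("unknown kingdom string(s): ",
                     paste(unique(md$kingdom[bad]), collapse = ", "))
  if (any(!nzchar(md$fasta_path) | is.na(md$fasta_path))) {
    stop("missing fasta_path in metadata")
  }
  ids <- sanitize_labels(md$genome_id)
  out <- data.frame(genome_id = as.character(ids), original_id = md$genome_id,
                    kingdom = k,
                    in_community = as.logical(md$in_community),
                    fasta_path = md$fasta_path, stringsAsFactors = FALSE)
  out$gff_path <- if ("gff_path" %in% names(md)) md$gff_path else NA_character_
  if (anyDuplicated(out$genome_id)) stop("duplicate genome ids in metadata")
  if (any(is.na(out$in_community))) stop("in_community must be true/false")
  out
}

#' Load a community of genomes from a metadata table
#'
#' Reads each genome's protein FASTA (paths relative to the metadata file)
#' and, when a GFF3 path is given, attaches gene coordinates.
#'
#' @param metadata_path path to the metadata TSV.
#' @return named list of `genome_record`s with the metadata data.frame as
#'   attribute `metadata`.
#' @export
load_community <- function(metadata_path) {
  md <- read_metadata(metadata_path)
  base <- dirname(metadata_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  genomes <- lapply(seq_len(nrow(md)), function(i) {
    g <- read_protein_fasta(resolve(md$fasta_path[i]), md$genome_id[i],
                            md$kingdom[i], md$in_community[i])
    if (!is.na(md$gff_path[i]) && nzchar(md$gff_path[i])) {
      g <- attach_coords(g, read_gene_coords(resolve(md$gff_path[i])))
    }
    g
  })
  names(genomes) <- md$genome_id
  attr(genomes, "metadata") <- md
  genomes
}

#' Read gene coordinates from GFF3
#'
#' Uses rtracklayer when available. Gene ids are taken from the `ID`
#' attribute and must match protein ids.
#'
#' @param path GFF3 path.
#' @return data.frame with `protein_id`, `contig`, `start`, `end`, `strand`.
#' @export
read_gene_coords <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(path))
  data.frame(protein_id = as.character(gr$ID),
             contig = as.character(gr$seqnames),
             start = gr$start, end = gr$end,
             strand = as.character(gr$strand),
             stringsAsFactors = FALSE)
}

attach_coords <- function(genome, coords) {
  m <- match(genome$proteins$protein_id, coords$protein_id)
  genome$proteins$contig <- coords$contig[m]
  genome$proteins$start <- coords$start[m]
  genome$proteins$end <- coords$end[m]
  genome$proteins$strand <- coords$strand[m]
  genome
}

#' Parse and serialize Newick, with validation
#'
#' @param tree_text Newick string.
#' @return `phylo` object; branch lengths and internal support labels are
#'   preserved by [write_newick()].
#' @export
read_newick <- function(tree_text) {
  tr <- if (file.exists(tree_text)) ape::read.tree(tree_text)
        else ape::read.tree(text = tree_text)
  if (is.null(tr)) stop("could not parse Newick (unbalanced parentheses?)")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' @rdname read_newick
#' @param tree `phylo` object.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, digits = 6) {
  ape::write.tree(tree, digits = digits)
}
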