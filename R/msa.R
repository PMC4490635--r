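# Progressive multiple alignment: k-mer guide distances, UPGMA guide tree,
# profile-profile global alignment with affine gaps.

#' K-mer distance matrix for a set of sequences
#'
#' `d(a, b) = 1 - shared_kmers / min_possible` where shared k-mers are
#' counted with multiplicity (sum over k-mers of the smaller count) and
#' `min_possible = min(len) - k + 1`. Sequences shorter than k fall back to
#' a normalized edit distance.
#'
#' @param seqs named character vector of residue strings.
#' @param k k-mer size.
#' @return symmetric distance matrix with zero diagonal.
#' @export
kmer_distance_matrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  stopifnot(n >= 2)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(NULL)
    table(substring(s, 1:(L - k + 1), k:L))
  })
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      li <- nchar(seqs[i]); lj <- nchar(seqs[j])
      if (is.null(km[[i]]) || is.null(km[[j]])) {
        d[i, j] <- d[j, i] <-
          as.numeric(utils::adist(seqs[i], seqs[j])) / max(li, lj)
      } else {
        common <- intersect(names(km[[i]]), names(km[[j]]))
        shared <- sum(pmin(km[[i]][common], km[[j]][common]))
        d[i, j] <- d[j, i] <- 1 - shared / (min(li, lj) - k + 1)
      }
    }
  }
  d
}

#' UPGMA guide tree with deterministic tie-breaks
#'
#' Average-linkage agglomeration; when two candidate merges are equally
#' close the pair whose lexicographically smallest member label comes first
#' wins, so the topology is reproducible across runs.
#'
#' @param d symmetric distance matrix with labels.
#' @return `phylo` tree (also carries the merge order used by
#'   [progressive_align()] as attribute `merges`).
#' @export
guide_tree <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  stopifnot(n >= 2, identical(rownames(d), colnames(d)))
  active <- as.list(seq_len(n))              # member leaf indices
  key <- vapply(seq_len(n), function(i) labels[i], "")
  sizes <- rep(1L, n)
  D <- d
  merges <- list()
  heights <- numeric(0)
  repeat {
    m <- length(active)
    if (m == 1) break
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      cand <- list(i = i, j = j, h = D[i, j],
                   k = paste(sort(c(key[i], key[j])), collapse = "\r"))
      if (is.null(best) || cand$h < best$h - 1e-12 ||
          (abs(cand$h - best$h) <= 1e-12 && cand$k < best$k)) best <- cand
    }
    i <- best$i; j <- best$j
    merges[[length(merges) + 1L]] <- list(left = active[[i]],
                                          right = active[[j]],
                                          height = best$h / 2)
    heights <- c(heights, best$h / 2)
    newrow <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    key <- c(key[keep], min(key[i], key[j]))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  tr <- merges_to_phylo(merges, labels)
  attr(tr, "merges") <- merges
  tr
}

merges_to_phylo <- function(merges, labels) {
  nw <- as.list(labels)
  hgt <- rep(0, length(labels))
  for (m in merges) {
    li <- m$left[1]; ri <- m$right[1]
    bl <- m$height - hgt[li]; br <- m$height - hgt[ri]
    nw[[li]] <- sprintf("(%s:%.8g,%s:%.8g)", nw[[li]], max(bl, 0),
                        nw[[ri]], max(br, 0))
    hgt[li] <- m$height
    nw[[ri]] <- NA
  }
  ape::read.tree(text = paste0(nw[[which(!is.na(nw))[1]]], ";"))
}

#' Progressive multiple alignment of a protein family
#'
#' Aligns sequences in guide-tree merge order by global profile-profile
#' alignment (BLOSUM62; column score is the mean pairwise substitution
#' score with gap-residue pairs scoring zero; affine gaps, same penalties
#' as the similarity search).
#'
#' @param seqs named character vector of residue strings.
#' @param guide optional guide tree from [guide_tree()]; computed from
#'   [kmer_distance_matrix()] when NULL.
#' @param gap_open,gap_extend affine gap penalties.
#' @param family_id label carried into the result.
#' @return object of class `protein_msa`: `family_id`, `rows` (named
#'   aligned strings), `n_cols`.
#' @export
progressive_align <- function(seqs, guide = NULL, gap_open = 11,
                              gap_extend = 1, family_id = NA_character_) {
  seqs <- vapply(seqs, normalize_residues, "")
  if (length(seqs) == 1) {
    return(new_msa(family_id, seqs))
  }
  if (is.null(guide)) guide <- guide_tree(kmer_distance_matrix(seqs))
  merges <- attr(guide, "merges")
  if (is.null(merges)) stop("guide tree lacks merge order; use guide_tree()")
  sub <- blosum62_matrix()
  # cluster alignments as character matrices (rows = sequences)
  aln <- lapply(seq_along(seqs), function(i) {
    m <- matrix(strsplit(seqs[i], "")[[1]], nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  })
  for (m in merges) {
    li <- m$left[1]; ri <- m$right[1]
    A <- aln[[li]]; B <- aln[[ri]]
    pa <- profile_of(A); pb <- profile_of(B)
    colsc <- t(pa) %*% sub %*% pb
    path <- cpp_nw_path(colsc, gap_open, gap_extend)
    aln[[li]] <- merge_by_ops(A, B, path$ops)
    aln[ri] <- list(NULL)   # keep slot so indices stay stable
  }
  final <- aln[[which(!vapply(aln, is.null, TRUE))[1]]]
  final <- final[names(seqs)[names(seqs) %in% rownames(final)], , drop = FALSE]
  rows <- apply(final, 1, paste, collapse = "")
  new_msa(family_id, rows)
}

profile_of <- function(A) {
  # 21 x n_cols residue frequency profile; gaps carry zero weight but the
  # denominator is the number of rows, so gappy columns score lower.
  n <- nrow(A)
  p <- matrix(0, length(ALPHABET), ncol(A))
  for (s in seq_along(ALPHABET)) p[s, ] <- colSums(A == ALPHABET[s]) / n
  p
}

merge_by_ops <- function(A, B, ops) {
  na <- nrow(A); nb <- nrow(B)
  out <- matrix("-", na + nb, length(ops))
  rownames(out) <- c(rownames(A), rownames(B))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op != 3L) { ia <- ia + 1L; out[1:na, k] <- A[, ia] }
    if (op != 2L) { ib <- ib + 1L; out[(na + 1):(na + nb), k] <- B[, ib] }
  }
  out
}

new_msa <- function(family_id, rows) {
  nc <- unique(nchar(rows))
  stopifnot(length(nc) == 1, nc >= 1)
  structure(list(family_id = family_id, rows = rows, n_cols = nc),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> %s: %d sequences x %d columns\n",
              x$family_id %||% "?", length(x$rows), x$n_cols))
  invisible(x)
}

#' Write an MSA as aligned FASTA
#' @param msa `protein_msa`.
#' @param path output path.
#' @export
write_msa_fasta <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(msa$rows)) cat(">", nm, "\n", msa$rows[[nm]], "\n",
                                  sep = "", file = con)
  invisible(path)
}

#' Write an MSA in relaxed PHYLIP format
#'
#' Relaxed: full sequence names followed by two spaces, sequential layout.
#' Useful for feeding external likelihood tools.
#' @param msa `protein_msa`.
#' @param path output path.
#' @export
write_msa_phylip <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf(" %d %d\n", length(msa$rows), msa$n_cols), file = con)
  for (nm in names(msa$rows)) {
    cat(nm, "  ", msa$rows[[nm]], "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Read an aligned FASTA into a `protein_msa`
#' @param path aligned FASTA.
#' @param family_id label.
#' @export
read_msa_fasta <- function(path, family_id = NA_character_) {
  aa <- Biostrings::readAAMultipleAlignment(path)
  rows <- as.character(aa)
  new_msa(family_id, rows)
}
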