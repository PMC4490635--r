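# Shared fixtures: random peptides, in-memory MSAs, toy genomes, and the
# independent alignment-enumeration oracle used against the DP kernels.

AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_peptide <- function(len) paste(sample(AA, len, replace = TRUE),
                                      collapse = "")

make_msa <- function(rows, family_id = "fam") {
  structure(list(family_id = family_id, rows = rows,
                 n_cols = unique(nchar(rows))),
            class = "protein_msa")
}

toy_genome <- function(id, seqs, kingdom = "bacteria", in_community = TRUE) {
  genome_record(id, kingdom, in_community,
                data.frame(protein_id = names(seqs), residues = unname(seqs),
                           stringsAsFactors = FALSE))
}

blosum <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Exhaustive enumeration of local alignments with affine gaps (a gap of
# length L costs open + L*ext). Recursion over alignment extensions from
# every start pair; exponential, usable only for short peptides. Written
# independently of the DP kernels.
enum_local_score <- function(a, b, sub, open = 11, ext = 1) {
  ea <- strsplit(a, "")[[1]]; eb <- strsplit(b, "")[[1]]
  la <- length(ea); lb <- length(eb)
  best <- 0
  rec <- function(i, j, sc, state) {
    best <<- max(best, sc)   # alignment may end here
    if (i < la && j < lb) rec(i + 1, j + 1, sc + sub[ea[i + 1], eb[j + 1]], 0L)
    if (i < la) rec(i + 1, j, sc - if (state == 1L) ext else open + ext, 1L)
    if (j < lb) rec(i, j + 1, sc - if (state == 2L) ext else open + ext, 2L)
  }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      rec(i, j, sub[ea[i], eb[j]], 0L)   # local alignments start on a match
    }
  }
  best
}

# simulate aligned gap-free rows under the packaged Dayhoff model
simulate_rows <- function(tree, n_sites, seed) {
  evolve_family(tree, dayhoff_model(), n_sites, seed = seed)
}

# Independent oracle: all-pairs scoring + direct mutual-argmax rule,
# applied in test code over the same hits the package computes per pair.
rbh_oracle <- function(genomes, config) {
  ids <- names(genomes)
  hits <- list()
  for (gi in ids) for (gj in ids) {
    if (gi >= gj) next
    pi <- genomes[[gi]]$proteins; pj <- genomes[[gj]]$proteins
    for (a in seq_len(nrow(pi))) for (b in seq_len(nrow(pj))) {
      h <- local_align(pi$residues[a], pj$residues[b])
      hits[[length(hits) + 1L]] <- data.frame(
        gi = gi, gj = gj, a = pi$protein_id[a], b = pj$protein_id[b],
        score = if (is.null(h)) 0 else h$raw_score,
        ev = if (is.null(h)) Inf else h$evalue,
        id = if (is.null(h)) 0 else h$identity,
        cov = if (is.null(h)) 0 else h$cover_short,
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  out <- list()
  for (gpair in unique(paste(hits$gi, hits$gj))) {
    hh <- hits[paste(hits$gi, hits$gj) == gpair, , drop = FALSE]
    for (a in unique(hh$a)) {
      ha <- hh[hh$a == a, , drop = FALSE]
      mx <- max(ha$score)
      if (mx <= 0 || sum(ha$score == mx) != 1) next
      b <- ha$b[ha$score == mx]
      hb <- hh[hh$b == b, , drop = FALSE]
      mxb <- max(hb$score)
      if (sum(hb$score == mxb) != 1 || hb$a[hb$score == mxb] != a) next
      row <- ha[ha$b == b, ]
      if (row$ev > config$evalue_max || row$id <= config$identity_min ||
          row$cov <= config$coverage_min) next
      out[[length(out) + 1L]] <- paste(row$gi, row$a, row$gj, row$b)
    }
  }
  sort(unlist(out))
}

toy_genomes <- function(seed, n_genomes = 3, n_prot = 5, len = 40,
                        mut = 0.15) {
  set.seed(seed)
  base <- replicate(n_prot, random_peptide(len))
  gs <- lapply(seq_len(n_genomes), function(g) {
    seqs <- vapply(base, function(s) {
      ch <- strsplit(s, "")[[1]]
      k <- rbinom(1, len, mut)
      if (k > 0) ch[sample(len, k)] <- sample(AA, k, replace = TRUE)
      paste(ch, collapse = "")
    }, "")
    names(seqs) <- sprintf("g%dp%d", g, seq_len(n_prot))
    toy_genome(sprintf("G%d", g), seqs,
               kingdom = if (g %% 2) "bacteria" else "archaea")
  })
  names(gs) <- sprintf("G%d", seq_len(n_genomes))
  gs
}

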