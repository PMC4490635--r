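# Tree machinery: Dayhoff substitution model, ML pairwise distances,
# neighbor joining, site likelihoods via Felsenstein pruning (phangorn),
# NNI maximum-likelihood search, bootstrap + majority-rule consensus, and
# tree restriction/rooting. ape and phangorn provide the standard
# algorithms behind this surface; the AU-test statistics live in autest.R.

#' The Dayhoff amino-acid substitution model
#'
#' Returns the 20-state Dayhoff model: exchangeabilities, stationary
#' frequencies, the generator Q normalized to one expected substitution per
#' site per unit time, and its symmetric eigendecomposition for computing
#' transition matrices. Rates and frequencies are taken from phangorn's
#' model tables so that simulation, closed-form checks and pruning
#' likelihoods share bit-identical parameters.
#'
#' @return object of class `aa_model` with fields `name`, `levels`, `bf`,
#'   `exch` (190 lower-triangle rates as a symmetric matrix), `Q`
#'   (normalized generator) and `eig`.
#' @export
dayhoff_model <- function() {
  if (!is.null(the$dayhoff)) return(the$dayhoff)
  tr <- ape::read.tree(text = "(S1:0.1,S2:0.1);")
  m <- matrix(c("A", "R"), nrow = 2, ncol = 1,
              dimnames = list(c("S1", "S2"), NULL))
  dat <- phangorn::phyDat(m, type = "AA")
  fit <- phangorn::pml(tr, dat, model = "Dayhoff")
  lv <- attr(dat, "levels")[1:20]
  bf <- fit$bf
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- fit$Q
  S <- S + t(S)
  Q <- S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(bf * diag(Q)))          # mean rate 1 substitution/site
  D <- diag(sqrt(bf)); Di <- diag(1 / sqrt(bf))
  ev <- eigen(D %*% Q %*% Di, symmetric = TRUE)
  the$dayhoff <- structure(
    list(name = "dayhoff", levels = lv, bf = stats::setNames(bf, lv),
         exch = S, Q = Q,
         eig = list(values = ev$values, right = Di %*% ev$vectors,
                    left = t(ev$vectors) %*% D)),
    class = "aa_model")
  the$dayhoff
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("<aa_model> %s (20 states, mean rate 1)\n", x$name))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model an [dayhoff_model()].
#' @param t branch length (expected substitutions/site), >= 0.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$eig$right %*% (exp(model$eig$values * t) * model$eig$left)
  P[P < 0] <- 0
  dimnames(P) <- list(model$levels, model$levels)
  P
}

# integer-encode an aligned row over the model states; NA for gaps/X
encode_states <- function(row, model) {
  match(strsplit(row, "")[[1]], model$levels)
}

#' Maximum-likelihood distance between two aligned rows
#'
#' Maximizes the likelihood `prod pi_x P_xy(t)` over shared ungapped
#' columns by bracketed 1-D optimization; capped at 10 substitutions/site.
#'
#' @param row_a,row_b aligned residue strings (same length).
#' @param model substitution model.
#' @param cap maximum distance.
#' @export
ml_pair_distance <- function(row_a, row_b, model = dayhoff_model(),
                             cap = 10) {
  xa <- encode_states(row_a, model)
  xb <- encode_states(row_b, model)
  ok <- !is.na(xa) & !is.na(xb)
  if (!any(ok)) stop("no shared ungapped columns")
  N <- matrix(0, 20, 20)
  tab <- table(factor(xa[ok], levels = 1:20), factor(xb[ok], levels = 1:20))
  N[] <- as.numeric(tab)
  nll <- function(t) {
    P <- prob_matrix(model, t)
    -sum(N * log(pmax(P * model$bf, 1e-300)))
  }
  opt <- stats::optimize(nll, c(0, cap), tol = 1e-8)
  cand <- c(0, opt$minimum, cap)
  cand[which.min(vapply(cand, nll, 0))]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (ape); taxa are ordered lexicographically first so equal
#' inputs give identical output regardless of input order.
#'
#' @param d symmetric distance matrix with labels (n >= 3).
#' @return unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  o <- order(rownames(d))
  tr <- ape::nj(d[o, o])
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

msa_phyDat <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$rows), ""))
  rownames(m) <- names(msa$rows)
  phangorn::phyDat(m, type = "AA")
}

prepare_tree <- function(tree) {
  tr <- if (length(tree$tip.label) >= 3) ape::unroot(tree) else tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

#' Per-site log-likelihoods of a tree given an alignment
#'
#' Felsenstein pruning under the Dayhoff model (via phangorn); gaps and X
#' are missing data (likelihood summed over states). Site pattern
#' compression is re-expanded so the vector aligns with alignment columns.
#' Minus-infinite site log-likelihoods are floored at -1e9.
#'
#' @param tree `phylo` with branch lengths; leaves must all have MSA rows.
#' @param msa `protein_msa`.
#' @param model substitution model (Dayhoff).
#' @return list of class `site_lnl`: `site_lnl` vector (one per column),
#'   `lnl` total, `tree`, `fit` (the phangorn fit).
#' @export
tree_lnL <- function(tree, msa, model = dayhoff_model()) {
  miss <- setdiff(tree$tip.label, names(msa$rows))
  if (length(miss)) stop("tree leaves without MSA rows: ",
                         paste(miss, collapse = ", "))
  dat <- msa_phyDat(msa)
  dat <- subset(dat, tree$tip.label)
  fit <- phangorn::pml(prepare_tree(tree), dat, model = "Dayhoff")
  site <- fit$siteLik[attr(dat, "index")]
  site <- pmax(site, -1e9)
  structure(list(site_lnl = site, lnl = sum(site), tree = fit$tree,
                 fit = fit), class = "site_lnl")
}

#' Optimize branch lengths on a fixed topology
#'
#' Cyclic per-branch optimization (phangorn) until the likelihood gain is
#' below tolerance; the likelihood never decreases across sweeps.
#'
#' @inheritParams tree_lnL
#' @return `site_lnl` list with optimized `tree`, `lnl`, `site_lnl`.
#' @export
optimize_branch_lengths <- function(tree, msa, model = dayhoff_model()) {
  if (length(tree$tip.label) == 2) {
    # a single branch: the 1-D problem solved by the ML pairwise distance
    d <- ml_pair_distance(msa$rows[[tree$tip.label[1]]],
                          msa$rows[[tree$tip.label[2]]], model)
    tree$edge.length <- rep(d / 2, nrow(tree$edge))
    return(tree_lnL(tree, msa, model))
  }
  dat <- msa_phyDat(msa)
  dat <- subset(dat, tree$tip.label)
  fit <- phangorn::pml(prepare_tree(tree), dat, model = "Dayhoff")
  o <- quiet_optim(fit, optNni = FALSE)
  if (!is.finite(o$logLik)) stop("non-finite likelihood for family ",
                                 msa$family_id %||% "?")
  site <- pmax(o$siteLik[attr(dat, "index")], -1e9)
  structure(list(site_lnl = site, lnl = o$logLik, tree = o$tree, fit = o),
            class = "site_lnl")
}

quiet_optim <- function(fit, optNni) {
  suppressMessages(suppressWarnings(
    phangorn::optim.pml(fit, optNni = optNni, optEdge = TRUE,
                        control = phangorn::pml.control(trace = 0,
                                                        epsilon = 1e-8,
                                                        maxit = 20))))
}

#' Maximum-likelihood gene tree search
#'
#' NJ starting tree on ML pairwise distances, then NNI hill climbing with
#' branch-length re-optimization; accepts a rearrangement only when the
#' log-likelihood improves. Three-taxon alignments return the unique
#' topology directly.
#'
#' @param msa `protein_msa` (>= 3 sequences).
#' @param model substitution model.
#' @param start_tree optional starting topology (skips the NJ step).
#' @return `site_lnl` list (best tree, total and per-site lnL).
#' @export
ml_search <- function(msa, model = dayhoff_model(), start_tree = NULL) {
  n <- length(msa$rows)
  if (n < 3) stop("need at least 3 sequences")
  if (is.null(start_tree)) {
    nms <- names(msa$rows)
    D <- matrix(0, n, n, dimnames = list(nms, nms))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- ml_pair_distance(msa$rows[[i]], msa$rows[[j]],
                                             model)
    }
    start_tree <- nj_tree(D)
  }
  dat <- msa_phyDat(msa)
  fit <- phangorn::pml(prepare_tree(start_tree), dat, model = "Dayhoff")
  o <- quiet_optim(fit, optNni = n >= 4)
  site <- pmax(o$siteLik[attr(dat, "index")], -1e9)
  structure(list(site_lnl = site, lnl = o$logLik, tree = o$tree, fit = o),
            class = "site_lnl")
}

#' Bootstrap gene trees and majority-rule consensus
#'
#' Resamples alignment columns i.i.d. with replacement at original length,
#' reruns the ML search per replicate, and returns the majority-rule (> 50%)
#' consensus with bipartition frequencies as node supports in [0, 1].
#'
#' @param msa `protein_msa`.
#' @param model substitution model.
#' @param B number of replicates.
#' @param seed RNG seed.
#' @param start_tree optional per-replicate starting topology (typically
#'   the family's ML tree).
#' @return list: `consensus` (`phylo` with `node.label` supports),
#'   `trees` (multiPhylo of replicate trees).
#' @export
bootstrap_consensus <- function(msa, model = dayhoff_model(), B = 100L,
                                seed = 1L, start_tree = NULL) {
  stopifnot(B >= 1)
  set.seed(seed)
  n <- msa$n_cols
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rows <- vapply(msa$rows, function(r) {
      paste(strsplit(r, "")[[1]][idx], collapse = "")
    }, "")
    rep_msa <- new_msa(msa$family_id, rows)
    trees[[b]] <- ml_search(rep_msa, model, start_tree = start_tree)$tree
  }
  class(trees) <- "multiPhylo"
  cons <- consensus_from_trees(trees)
  list(consensus = cons, trees = trees)
}

#' Majority-rule consensus with supports from a list of trees
#'
#' Contains exactly the bipartitions present in more than half of the
#' input trees; node labels give each bipartition's frequency.
#'
#' @param trees multiPhylo over one leaf set.
#' @return `phylo` (possibly multifurcating) with numeric `node.label`.
#' @export
consensus_from_trees <- function(trees) {
  labs <- sort(trees[[1]]$tip.label)
  freq <- split_frequencies(trees)
  keep <- names(freq)[freq > 0.5]
  build_tree_from_clades(labs, keep, freq[keep])
}

#' Bipartition frequencies across a set of trees
#' @param trees multiPhylo over one leaf set.
#' @return named numeric vector of frequencies in [0, 1], keyed by
#'   canonical split strings (see [tree_splits()]).
#' @export
split_frequencies <- function(trees) {
  counts <- list()
  for (tr in trees) {
    for (s in tree_splits(tr)) counts[[s]] <- (counts[[s]] %||% 0) + 1
  }
  if (!length(counts)) return(stats::setNames(numeric(0), character(0)))
  unlist(counts) / length(trees)
}

#' Collapse tree branches whose bootstrap support is below a threshold
#'
#' Each internal edge's split is looked up in the replicate split
#' frequencies; edges below the threshold collapse into polytomies.
#' Branch lengths of retained edges are kept.
#'
#' @param tree `phylo` (typically the family's ML gene tree).
#' @param freq named split-frequency vector from [split_frequencies()].
#' @param threshold support below which an edge is collapsed.
#' @return possibly multifurcating `phylo`.
#' @export
collapse_unsupported <- function(tree, freq, threshold) {
  n <- length(tree$tip.label)
  if (n < 4) return(tree)
  ref <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  tr <- tree
  for (i in seq_along(pp)) {
    node <- n + i
    side <- labs[pp[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) next
    key <- paste(sort(side), collapse = ",")
    sup <- if (key %in% names(freq)) freq[[key]] else 0
    if (sup < threshold) {
      tr$edge.length[tr$edge[, 2] == node] <- 0
    }
  }
  ape::di2multi(tr, tol = 1e-12)
}

# Canonical non-trivial splits of a tree: each split is represented by the
# side NOT containing the alphabetically first taxon, as a sorted
# comma-joined string.
#' Canonical bipartition set of a tree
#' @param tree `phylo`.
#' @return character vector of canonical split strings.
#' @export
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  ref <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(sort(side), collapse = ","))
    }
  }
  unique(out)
}

# Assemble a tree from a laminar family of clades (split sides not
# containing the alphabetically first taxon); used by the consensus
# builder. Majority-rule splits are pairwise compatible, so the sides are
# nested or disjoint and assemble into a unique multifurcating tree.
build_tree_from_clades <- function(labs, clades, freqs) {
  ref <- sort(labs)[1]
  sets <- lapply(clades, function(s) strsplit(s, ",")[[1]])
  assemble <- function(taxa, idx) {
    maximal <- idx[vapply(idx, function(k) {
      !any(vapply(idx, function(m) {
        m != k && length(sets[[m]]) > length(sets[[k]]) &&
          all(sets[[k]] %in% sets[[m]])
      }, TRUE))
    }, TRUE)]
    parts <- character(0)
    covered <- character(0)
    for (k in maximal) {
      s <- sets[[k]]
      inner <- setdiff(idx, k)
      inner <- inner[vapply(inner, function(m) {
        all(sets[[m]] %in% s) && length(sets[[m]]) < length(s)
      }, TRUE)]
      parts <- c(parts, sprintf("(%s)%.3f", assemble(s, inner), freqs[k]))
      covered <- c(covered, s)
    }
    singles <- setdiff(taxa, covered)
    paste(c(parts, sort(singles)), collapse = ",")
  }
  txt <- if (!length(sets)) {
    sprintf("(%s);", paste(sort(labs), collapse = ","))
  } else {
    sprintf("(%s,%s);", ref, assemble(setdiff(labs, ref), seq_along(sets)))
  }
  ape::read.tree(text = txt)
}

#' Load and validate the organism (species) tree
#'
#' Accepts a Newick file/string, a `phylo`, or an aligned 16S rRNA FASTA
#' (one sequence per genome, names = genome ids) from which a
#' maximum-likelihood tree is built. Leaf labels are sanitized and must
#' equal the metadata's genome set exactly.
#'
#' @param input Newick path/string, aligned rRNA FASTA path, or `phylo`.
#' @param genome_ids expected leaf set.
#' @return rooted `phylo`.
#' @export
species_tree <- function(input, genome_ids) {
  if (is.character(input) && length(input) == 1 && file.exists(input) &&
      grepl("^>", readLines(input, n = 1))) {
    return(species_tree(species_tree_from_rrna(input), genome_ids))
  }
  tr <- if (inherits(input, "phylo")) input else read_newick(input)
  tr$tip.label <- as.character(sanitize_labels(tr$tip.label))
  miss <- setdiff(genome_ids, tr$tip.label)
  extra <- setdiff(tr$tip.label, genome_ids)
  if (length(miss) || length(extra)) {
    stop("species tree leaf set mismatch; missing: ",
         paste(miss, collapse = ", "), "; unexpected: ",
         paste(extra, collapse = ", "))
  }
  tr
}

#' Build an organism tree from an aligned 16S rRNA FASTA
#'
#' Neighbor joining on ML distances followed by NNI search under GTR,
#' midpoint-rooted. The alignment must already be aligned (equal lengths),
#' with one sequence per genome named by genome id.
#'
#' @param path aligned rRNA FASTA.
#' @return rooted `phylo`.
#' @export
species_tree_from_rrna <- function(path) {
  dat <- phangorn::read.phyDat(path, format = "fasta", type = "DNA")
  tr <- ape::nj(phangorn::dist.ml(dat))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  fit <- phangorn::pml(tr, dat, model = "GTR", k = 1)
  o <- suppressMessages(suppressWarnings(
    phangorn::optim.pml(fit, optNni = TRUE, optEdge = TRUE, optQ = TRUE,
                        optBf = TRUE,
                        control = phangorn::pml.control(trace = 0))))
  phangorn::midpoint(o$tree)
}

#' Restrict a tree to a taxon subset
#'
#' Preserves the induced topology and path lengths between kept leaves.
#' @param tree `phylo`.
#' @param taxa leaves to keep (subset of the tree's leaves).
#' @export
restrict_tree <- function(tree, taxa) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("taxa not in tree: ", paste(miss, collapse = ", "))
  ape::keep.tip(tree, taxa)
}

#' Root a tree with an outgroup, with midpoint fallback
#'
#' Places the root on the outgroup's stem branch. A non-monophyletic
#' outgroup triggers a warning and midpoint rooting.
#'
#' @param tree unrooted `phylo`.
#' @param outgroup_leaves leaf labels.
#' @export
root_with_outgroup <- function(tree, outgroup_leaves) {
  outgroup_leaves <- intersect(outgroup_leaves, tree$tip.label)
  if (!length(outgroup_leaves)) {
    warning("no outgroup leaves present; midpoint rooting")
    return(phangorn::midpoint(tree))
  }
  rooted <- tryCatch({
    if (!ape::is.monophyletic(tree, outgroup_leaves)) stop("not monophyletic")
    ape::root(tree, outgroup = outgroup_leaves, resolve.root = TRUE)
  }, error = function(e) NULL)
  if (is.null(rooted)) {
    warning("outgroup not monophyletic; midpoint rooting")
    rooted <- phangorn::midpoint(tree)
  }
  rooted
}
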