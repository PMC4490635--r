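# Approximately unbiased (AU) test of the organism-tree topology per
# family: multiscale RELL bootstrap of per-site log-likelihood differences
# and weighted least-squares fitting of the signed distance d and curvature
# c, with p_au = 1 - Phi(d - c).

#' Site likelihoods under the species-constrained topology
#'
#' Restricts the organism tree to the family's taxa, re-optimizes branch
#' lengths on the family alignment, and returns the per-site
#' log-likelihoods with the same column indexing as the gene-tree vector.
#'
#' @param msa `protein_msa`.
#' @param species `phylo` organism tree (superset of the family's taxa).
#' @param model substitution model.
#' @return `site_lnl` list.
#' @export
constrained_fit <- function(msa, species, model = dayhoff_model()) {
  topo <- restrict_tree(species, names(msa$rows))
  optimize_branch_lengths(ape::unroot(topo), msa, model)
}

#' Multiscale RELL bootstrap of the species topology's support
#'
#' At each scale r the per-site log-likelihood vectors are resampled
#' (round(n*r) sites with replacement, B times) and the bootstrap
#' proportion BP(r) is the fraction of resamples in which the species
#' topology's total is at least the gene topology's (ties count for the
#' species topology). Each scale uses an independent seeded RNG stream.
#'
#' @param sl_gene,sl_species equal-length per-site log-likelihood vectors.
#' @param scales relative resample sizes.
#' @param B resamples per scale.
#' @param seed base seed.
#' @return data.frame with columns `scale`, `m`, `B`, `bp`; attribute
#'   `low_confidence` when fewer than 10 sites.
#' @export
rell_multiscale <- function(sl_gene, sl_species,
                            scales = seq(0.5, 1.4, by = 0.1), B = 1000L,
                            seed = 1L) {
  stopifnot(length(sl_gene) == length(sl_species), all(scales > 0), B >= 100)
  n <- length(sl_gene)
  low <- n < 10
  if (low) warning("fewer than 10 sites; RELL result is low-confidence")
  delta <- sl_species - sl_gene
  bp <- numeric(length(scales))
  m <- integer(length(scales))
  for (k in seq_along(scales)) {
    m[k] <- max(1L, as.integer(round(n * scales[k])))
    set.seed(stage_seed(seed, "rell", k))
    W <- stats::rmultinom(B, m[k], rep(1 / n, n))
    stat <- as.numeric(crossprod(W, delta))
    bp[k] <- mean(stat >= 0)
  }
  out <- data.frame(scale = scales, m = m, B = B, bp = bp)
  attr(out, "low_confidence") <- low
  out
}

#' Fit the AU model to a multiscale bootstrap curve
#'
#' Fits the multiscale model `psi(sigma^2) = sigma * qnorm(1 - BP) =
#' d + c * sigma^2` (equivalently `z = d / sigma + c * sigma`) with
#' `sigma = sqrt(1/r)`, by one-pass weighted least squares (weights
#' `B * phi(z)^2 / (BP (1 - BP))` after clamping BP into
#' `[1/(2B), 1 - 1/(2B)]`); `d` is the signed distance and `c` the
#' boundary curvature, and `p_au = 1 - pnorm(d - c)`. Requires at least 3
#' scales with BP strictly inside (0, 1); otherwise falls back to the
#' naive bootstrap proportion with a degenerate flag.
#'
#' @param bp_curve data.frame from [rell_multiscale()].
#' @return list: `d`, `c`, `se_d`, `se_c`, `p_au`, `p_bp`, `degenerate`.
#' @export
fit_au <- function(bp_curve) {
  r <- bp_curve$scale; bp <- bp_curve$bp; B <- bp_curve$B
  p_bp <- bp[which.min(abs(r - 1))]
  usable <- bp > 0 & bp < 1
  if (sum(usable) < 3) {
    return(list(d = NA_real_, c = NA_real_, se_d = NA_real_,
                se_c = NA_real_, p_au = p_bp, p_bp = p_bp,
                degenerate = TRUE))
  }
  r <- r[usable]; bp <- bp[usable]; B <- B[usable]
  bp <- pmin(pmax(bp, 1 / (2 * B)), 1 - 1 / (2 * B))
  z <- stats::qnorm(1 - bp)
  sigma <- sqrt(1 / r)
  X <- cbind(1 / sigma, sigma)
  w <- B * stats::dnorm(z)^2 / (bp * (1 - bp))
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * z))
  covb <- solve(XtWX)
  d <- beta[1]; cc <- beta[2]
  list(d = d, c = cc, se_d = sqrt(covb[1, 1]), se_c = sqrt(covb[2, 2]),
       p_au = min(max(stats::pnorm(d - cc, lower.tail = FALSE), 0), 1),
       p_bp = p_bp, degenerate = FALSE)
}

#' AU test of one ortholog family against the organism tree
#'
#' Runs the gene-tree ML search, the species-constrained fit, the
#' multiscale RELL bootstrap and the (d, c) fit. When the gene ML topology
#' equals the constrained topology the species tree cannot be rejected and
#' p_au = 1 by construction.
#'
#' @param msa family alignment (`protein_msa`).
#' @param species organism tree.
#' @param config an [hgt_config()].
#' @param model substitution model.
#' @param seed RNG seed for the RELL stage.
#' @return object of class `au_result`: family id, per-topology lnL, the
#'   BP curve, fitted d/c, `p_au`, `p_bp`, `rejected`, and the two trees.
#' @export
test_family <- function(msa, species, config = hgt_config(),
                        model = dayhoff_model(), seed = config$seed) {
  gene <- ml_search(msa, model)
  cons <- constrained_fit(msa, species, model)
  same <- setequal(tree_splits(gene$tree), tree_splits(cons$tree))
  if (!same && cons$lnl > gene$lnl + 1e-6) {
    # NNI search missed the constrained optimum; the species topology is
    # then at least as good and cannot be rejected
    gene <- cons
    same <- TRUE
  }
  if (same) {
    res <- list(d = NA_real_, c = NA_real_, se_d = NA_real_,
                se_c = NA_real_, p_au = 1, p_bp = 1, degenerate = FALSE)
    curve <- NULL
  } else {
    curve <- rell_multiscale(gene$site_lnl, cons$site_lnl,
                             scales = config$scales, B = config$rell_B,
                             seed = seed)
    res <- fit_au(curve)
  }
  structure(list(family_id = msa$family_id, lnl_gene = gene$lnl,
                 lnl_species = cons$lnl, gene_tree = gene$tree,
                 species_topology = cons$tree, gene_site_lnl = gene$site_lnl,
                 species_site_lnl = cons$site_lnl, bp_curve = curve,
                 d = res$d, c = res$c, se_d = res$se_d, se_c = res$se_c,
                 p_au = res$p_au, p_bp = res$p_bp,
                 degenerate = res$degenerate,
                 topologies_identical = same,
                 rejected = res$p_au < config$alpha),
            class = "au_result")
}

#' @export
print.au_result <- function(x, ...) {
  cat(sprintf("<au_result> %s: lnL gene %.2f vs species %.2f, p_au = %.4g%s\n",
              x$family_id %||% "?", x$lnl_gene, x$lnl_species, x$p_au,
              if (x$rejected) " (rejected)" else ""))
  invisible(x)
}

#' Write/read the per-site log-likelihood TSV interchange format
#'
#' Columns `family_id`, `topology_id`, `site`, `lnl`; lets externally
#' computed site likelihoods be fed to the AU stage.
#'
#' @param site_lnls named list (topology_id -> numeric vector).
#' @param family_id family label.
#' @param path output path.
#' @param config run config for the provenance header.
#' @export
write_site_lnl <- function(site_lnls, family_id, path, config = NULL) {
  df <- do.call(rbind, lapply(names(site_lnls), function(tp) {
    data.frame(family_id = family_id, topology_id = tp,
               site = seq_along(site_lnls[[tp]]), lnl = site_lnls[[tp]],
               stringsAsFactors = FALSE)
  }))
  write_tsv_headered(df, path, config)
}

#' @rdname write_site_lnl
#' @export
read_site_lnl <- function(path) {
  df <- read_tsv_headered(path)
  split(df, df$family_id)
}

#' AU test from externally supplied site likelihoods
#'
#' @param sl_gene,sl_species per-site log-likelihood vectors.
#' @param config an [hgt_config()].
#' @param seed RNG seed.
#' @return list with `p_au`, `p_bp`, `d`, `c`, `rejected`.
#' @export
au_from_site_lnl <- function(sl_gene, sl_species, config = hgt_config(),
                             seed = config$seed) {
  curve <- rell_multiscale(sl_gene, sl_species, scales = config$scales,
                           B = config$rell_B, seed = seed)
  res <- fit_au(curve)
  res$rejected <- res$p_au < config$alpha
  res$bp_curve <- curve
  res
}
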