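#' Principal component analysis of the IBS matrix
#'
#' Eigendecomposition of the double-centered identity-by-state matrix.
#' Because centering turns the IBS matrix into a Gram matrix of centered
#' genotype scores, the component scores reproduce the IBS-derived pairwise
#' distances (Gower's principal coordinates property).
#'
#' @param K a [kinship()] of kind `"ibs"`.
#' @return an object of class `structure_result` with `eigenvalues`
#'   (descending), `pct_variance` (sums to 100 over non-negative
#'   eigenvalues), `scores` (genotypes x components, eigenvectors scaled by
#'   `sqrt(eigenvalue)`), `n_genotypes`, and a `degenerate` flag set when the
#'   spectrum is numerically zero (all genotypes identical).
#' @export
pca_ibs <- function(K) {
  stopifnot(inherits(K, "kinship"))
  if (K$kind != "ibs") stop_fatal("pca_ibs expects an IBS kinship")
  A <- K$values
  n <- nrow(A)
  rm_ <- rowMeans(A)
  B <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- pmax(ev, 0)
  total <- sum(pos)
  degenerate <- total < n * 1e-12
  pct <- if (degenerate) rep(0, n) else 100 * pos / total
  scores <- e$vectors %*% diag(sqrt(pos), n, n)
  dimnames(scores) <- list(K$ids, paste0("PC", seq_len(n)))
  structure(
    list(eigenvalues = ev, pct_variance = pct, scores = scores,
         n_genotypes = n, degenerate = degenerate,
         n_significant = NA_integer_, n_subpops = NA_integer_),
    class = "structure_result"
  )
}

#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf("structure_result: %d genotypes; PC1 %.2f%%, PC2 %.2f%%",
              x$n_genotypes, x$pct_variance[1],
              if (length(x$pct_variance) > 1) x$pct_variance[2] else NA))
  if (!is.na(x$n_subpops)) {
    cat(sprintf("; %d significant PC(s), %d subpopulation(s)",
                x$n_significant, x$n_subpops))
  }
  if (x$degenerate) cat(" [degenerate spectrum]")
  cat("\n")
  invisible(x)
}

#' Plot leading principal components
#'
#' Pairwise scatter of the first `npc` IBS-PCA scores, optionally colored by
#' subpopulation.
#' @param x a `structure_result`.
#' @param assignment optional [subpop_assignment()] for coloring.
#' @param npc number of leading components (default 3).
#' @param ... passed to [graphics::pairs()]/[graphics::plot()].
#' @export
plot.structure_result <- function(x, assignment = NULL, npc = 3, ...) {
  npc <- min(npc, ncol(x$scores))
  col <- 1
  if (!is.null(assignment)) {
    col <- as.integer(factor(assignment$groups[rownames(x$scores)]))
  }
  if (npc >= 2) {
    graphics::pairs(x$scores[, seq_len(npc), drop = FALSE], col = col, ...)
  } else {
    graphics::plot(x$scores[, 1], col = col, ylab = "PC1", ...)
  }
  invisible(x)
}

# Tracy-Widom (TW1) critical values at the supported significance levels.
tw_critical <- c("0.05" = 0.9793, "0.01" = 2.0234)

#' Marker-standardized genotype spectrum for significance testing
#'
#' Eigenvalues of the sample covariance of the marker-standardized genotype
#' matrix (each marker centered at its mean dosage and scaled by
#' `sqrt(p (1 - p))`). The Tracy-Widom edge theory assumes homoskedastic
#' entries, which raw dosage columns are not (their variance varies with
#' allele frequency), so subpopulation counting is performed on this
#' standardized spectrum while [pca_ibs()] stays on the literal IBS matrix
#' for scores and variance shares.
#'
#' @param panel an imputed [marker_panel()] with all markers polymorphic.
#' @return eigenvalues in decreasing order.
#' @export
patterson_eigenvalues <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  assert_imputed(panel)
  p <- allele_freq(panel)
  mono <- p <= 0 | p >= 1
  d <- panel$dosage[, !mono, drop = FALSE]
  p <- p[!mono]
  if (!length(p)) stop_fatal("no polymorphic markers")
  X <- sweep(d, 2, 2 * p)
  X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  eigen(tcrossprod(X) / length(p), symmetric = TRUE, only.values = TRUE)$values
}

#' Count significant principal components (Tracy-Widom)
#'
#' Sequentially tests the leading eigenvalues of the IBS-PCA spectrum
#' against the Tracy-Widom TW1 distribution, using the moment-based
#' effective-marker-count normalization of the eigenanalysis literature:
#' for the `m` remaining eigenvalues `l_i`,
#' `n' = ((m + 1) * S1^2) / ((m - 1) * S2 - S1^2)` with `S1 = sum(l_i)`,
#' `S2 = sum(l_i^2)`; the test statistic for the top remaining eigenvalue is
#' `(m * l_1 / S1 - mu) / sigma` with the usual centering and scaling
#' constants in `n'` and `m`. Testing stops at the first non-significant
#' component. The number of subpopulations is the significant count plus one.
#'
#' @param eigenvalues spectrum from [pca_ibs()] (descending).
#' @param n_markers marker count; only used as a fallback effective count if
#'   the moment estimator degenerates.
#' @param alpha significance level, `0.05` or `0.01`.
#' @return integer count of significant components.
#' @export
tracy_widom_count <- function(eigenvalues, n_markers = NULL, alpha = 0.05) {
  key <- format(alpha)
  if (!key %in% names(tw_critical)) {
    stop_fatal("alpha must be 0.05 or 0.01")
  }
  crit <- tw_critical[[key]]
  ev <- eigenvalues[eigenvalues > max(eigenvalues) * 1e-9]
  if (length(eigenvalues) < 3) stop_fatal("need at least 3 eigenvalues")
  count <- 0L
  while (length(ev) - count >= 3) {
    l <- ev[(count + 1L):length(ev)]
    m <- length(l)
    s1 <- sum(l)
    s2 <- sum(l^2)
    # moment estimator of the effective marker count: matches E[tr W] and
    # E[tr W^2] of a Wishart(n', I_m) spectrum
    denom <- m * s2 - s1^2
    np <- if (denom > 0) (m + 1) * s1^2 / denom else (n_markers %||% m)
    if (!is.finite(np) || np <= 1) break
    mu <- (sqrt(np - 1) + sqrt(m))^2 / np
    sg <- ((sqrt(np - 1) + sqrt(m)) / np) *
      (1 / sqrt(np - 1) + 1 / sqrt(m))^(1 / 3)
    x <- (m * l[1] / s1 - mu) / sg
    if (x > crit) count <- count + 1L else break
  }
  count
}

#' Subpopulation assignment
#'
#' @param groups named character/factor vector mapping genotype id to group
#'   label; every genotype appears exactly once.
#' @return object of class `subpop_assignment` with `groups` (named
#'   character), `sizes` (table) and `S` (group count).
#' @export
subpop_assignment <- function(groups) {
  if (is.null(names(groups))) stop_fatal("groups must be named by genotype id")
  if (anyDuplicated(names(groups))) stop_fatal("duplicate genotype ids")
  groups <- stats::setNames(as.character(groups), names(groups))
  sizes <- table(groups)
  structure(list(groups = groups, sizes = sizes, S = length(sizes)),
            class = "subpop_assignment")
}

#' @export
print.subpop_assignment <- function(x, ...) {
  cat(sprintf("subpop_assignment: %d genotypes in %d group(s) [%s]\n",
              length(x$groups), x$S,
              paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", ")))
  invisible(x)
}

#' Assign genotypes to subpopulations
#'
#' k-means on the first `k - 1` IBS-PCA score dimensions (1 dimension when
#' `k = 2`; `k = 1` returns a single group without clustering), with 25
#' random restarts under a fixed seed so labels are arbitrary but stable.
#'
#' @param structure a `structure_result` from [pca_ibs()].
#' @param k number of groups, typically [tracy_widom_count()] plus one.
#' @param seed RNG seed for the restarts.
#' @return a [subpop_assignment()].
#' @export
assign_subpopulations <- function(structure, k, seed = 1L) {
  stopifnot(inherits(structure, "structure_result"), k >= 1)
  ids <- rownames(structure$scores)
  if (k > length(ids)) stop_fatal("k exceeds the number of genotypes")
  if (k == 1) {
    return(subpop_assignment(stats::setNames(rep("1", length(ids)), ids)))
  }
  ndim <- max(1L, k - 1L)
  sc <- structure$scores[, seq_len(min(ndim, ncol(structure$scores))), drop = FALSE]
  km <- with_seed(seed, stats::kmeans(sc, centers = k, nstart = 25, iter.max = 100))
  subpop_assignment(stats::setNames(as.character(km$cluster), ids))
}

#' Weir-Cockerham Fst
#'
#' Multi-population fixation index from the diploid variance-component
#' estimator: per locus the among-population (`a`), among-individual (`b`)
#' and within-individual (`c`) components are computed from subpopulation
#' sample sizes, allele frequencies and observed heterozygote frequencies,
#' and the panel estimate is the ratio of sums `sum(a) / sum(a + b + c)`.
#' Loci with a zero total are skipped. For fully inbred lines the observed
#' heterozygosity is zero and `c` vanishes.
#'
#' @param panel an imputed [marker_panel()].
#' @param assignment a [subpop_assignment()] with at least two groups of at
#'   least two genotypes each.
#' @return Fst estimate (scalar).
#' @export
fst_weir_cockerham <- function(panel, assignment) {
  stopifnot(inherits(panel, "marker_panel"),
            inherits(assignment, "subpop_assignment"))
  assert_imputed(panel)
  g <- assignment$groups[panel$genotype_ids]
  if (anyNA(g)) stop_fatal("assignment does not cover every panel genotype")
  if (assignment$S < 2) stop_fatal("need at least two subpopulations")
  if (any(assignment$sizes < 2)) stop_fatal("each group needs >= 2 genotypes")

  f <- factor(g)
  r <- nlevels(f)
  n_i <- as.vector(table(f))                       # diploid counts per group
  d <- panel$dosage
  # per-group allele and heterozygote frequencies, loci in columns
  p_i <- rowsum(d, f) / (2 * n_i)                  # r x K
  h_i <- rowsum((d == 1) + 0, f) / n_i             # r x K

  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  tot <- a + b + cc
  keep <- is.finite(tot) & abs(tot) > 1e-12
  if (!any(keep)) stop_fatal("every locus skipped (zero denominators)")
  sum(a[keep]) / sum(tot[keep])
}

#' One-call population-structure characterization
#'
#' Convenience wrapper chaining [ibs_matrix()], [pca_ibs()],
#' [tracy_widom_count()], [assign_subpopulations()] and
#' [fst_weir_cockerham()].
#'
#' @param panel an imputed [marker_panel()].
#' @param alpha Tracy-Widom significance level.
#' @param seed seed for the k-means assignment.
#' @return list with `structure` (a `structure_result` whose
#'   `n_significant`/`n_subpops` are filled in), `assignment`, and `fst`
#'   (`NA` when a single subpopulation is inferred).
#' @export
characterize_structure <- function(panel, alpha = 0.05, seed = 1L) {
  K <- ibs_matrix(panel)
  st <- pca_ibs(K)
  st$n_significant <- tracy_widom_count(patterson_eigenvalues(panel),
                                        panel$K, alpha)
  st$n_subpops <- st$n_significant + 1L
  asg <- assign_subpopulations(st, st$n_subpops, seed = seed)
  fst <- if (asg$S >= 2 && all(asg$sizes >= 2)) {
    fst_weir_cockerham(panel, asg)
  } else {
    NA_real_
  }
  list(structure = st, assignment = asg, fst = fst)
}
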