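#' Kinship matrix container
#'
#' Wraps a symmetric genotype-by-genotype relationship matrix with a tag
#' saying which relationship it is (`ibs`, `additive_ab`,
#' `additive_ab_masked`, `gaussian`, `loco`) and method metadata (Gaussian
#' bandwidth `theta`, the excluded chromosome of a leave-one-chromosome-out
#' matrix, the masked map windows of a QTL-masked matrix).
#'
#' @param values symmetric numeric matrix with genotype ids as dimnames.
#' @param kind relationship tag.
#' @param meta list of method metadata.
#' @return an object of class `kinship`.
#' @export
kinship <- function(values,
                    kind = c("ibs", "additive_ab", "additive_ab_masked",
                             "gaussian", "loco"),
                    meta = list()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop_fatal("kinship needs genotype dimnames")
  if (nrow(values) != ncol(values) ||
      max(abs(values - t(values))) > 1e-10) {
    stop_fatal("kinship matrix must be symmetric")
  }
  values <- (values + t(values)) / 2
  if (any(!is.finite(values))) stop_fatal("kinship entries must be finite")
  structure(
    list(ids = rownames(values), values = values, kind = kind, meta = meta),
    class = "kinship"
  )
}

#' @export
print.kinship <- function(x, ...) {
  extra <- ""
  if (!is.null(x$meta$theta)) extra <- sprintf(", theta = %g", x$meta$theta)
  if (!is.null(x$meta$excluded_chromosome)) {
    extra <- sprintf(", excluding chromosome %s", x$meta$excluded_chromosome)
  }
  cat(sprintf("kinship [%s]: %d genotypes%s\n", x$kind, length(x$ids), extra))
  invisible(x)
}

#' Write / read a kinship matrix as CSV
#'
#' Plain interchange format: genotype ids as header and first column.
#' @param K a [kinship()].
#' @param path CSV file.
#' @param kind relationship tag used when reading back.
#' @return `write_kinship` the path, invisibly; `read_kinship` a [kinship()].
#' @export
write_kinship <- function(K, path) {
  stopifnot(inherits(K, "kinship"))
  dt <- data.table::data.table(genotype_id = K$ids)
  dt <- cbind(dt, data.table::as.data.table(K$values))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path, kind = "additive_ab") {
  dt <- as.data.frame(data.table::fread(path, header = TRUE))
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1])
  dimnames(m) <- list(ids, ids)
  kinship(m, kind = kind)
}

assert_imputed <- function(panel) {
  if (anyNA(panel$dosage)) {
    stop_fatal("panel has missing calls; run impute_missing() first")
  }
}

#' Identity-by-state relationship matrix
#'
#' Proportion of alleles shared between genotypes:
#' `A_IBS = (G G' + G2 G2') / K` with `G = dosage / 2` (scores 0 and 1 for
#' the homozygotes, 0.5 for heterozygotes), `G2 = 1 - G`, and `K` the marker
#' count. Entries lie in \[0, 1\]; a fully homozygous genotype has self-IBS 1
#' while a heterozygous call contributes 0.5 to its own diagonal — the
#' formula is applied literally.
#'
#' @param panel an imputed [marker_panel()].
#' @return a [kinship()] of kind `"ibs"`.
#' @export
ibs_matrix <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  assert_imputed(panel)
  if (panel$K == 0) stop_fatal("panel has no markers")
  G <- panel$dosage / 2
  A <- (tcrossprod(G) + tcrossprod(1 - G)) / panel$K
  kinship(A, kind = "ibs")
}

#' Realized additive relationship matrix
#'
#' Marker-based additive relationship with typical entry
#' `A_ij = (1/K) * sum_k (G_ik - 2 p_k)(G_jk - 2 p_k) / (2 p_k (1 - p_k))`,
#' where `G_ik` is the 0/1/2 dosage and `p_k` the allele frequency of marker
#' `k` in the panel passed in. Frequencies always come from this calibration
#' panel, never from a training subset.
#'
#' @param panel an imputed [marker_panel()] with every marker polymorphic.
#' @param kind tag for the result (used by the leave-one-chromosome-out and
#'   masked wrappers).
#' @param meta metadata list forwarded to [kinship()].
#' @return a [kinship()] of kind `"additive_ab"` by default.
#' @export
additive_relationship <- function(panel, kind = "additive_ab", meta = list()) {
  stopifnot(inherits(panel, "marker_panel"))
  assert_imputed(panel)
  p <- allele_freq(panel)
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop_fatal("monomorphic marker(s) give a zero denominator: ",
               paste(utils::head(names(p)[mono], 5), collapse = ", "))
  }
  W <- sweep(panel$dosage, 2, 2 * p)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(W) / panel$K
  kinship(A, kind = kind, meta = meta)
}

# Squared Euclidean distances on dosage scores, scaled so the mean
# off-diagonal distance is 1; makes the theta grid transferable across panels.
scaled_sq_dist <- function(panel) {
  assert_imputed(panel)
  D <- as.matrix(stats::dist(panel$dosage))^2
  n <- nrow(D)
  if (n < 2) stop_fatal("need at least two genotypes")
  off_mean <- sum(D) / (n * (n - 1))
  if (off_mean <= 0) stop_fatal("all genotypes identical: degenerate kernel")
  D / off_mean
}

#' Gaussian relationship kernel
#'
#' `A* = exp(-D / theta)` where `D` holds squared Euclidean dissimilarities
#' between dosage vectors, scaled by their off-diagonal mean so that the mean
#' scaled distance is 1 and the conventional bandwidth grid 0.05-5 means the
#' same thing on any panel. The diagonal is exactly 1.
#'
#' @param panel an imputed [marker_panel()].
#' @param theta positive bandwidth; larger values decay more slowly.
#' @return a [kinship()] of kind `"gaussian"` with `meta$theta` set.
#' @export
gaussian_kernel <- function(panel, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  D <- scaled_sq_dist(panel)
  kinship(exp(-D / theta), kind = "gaussian", meta = list(theta = theta))
}

#' Leave-one-chromosome-out kinships
#'
#' One additive relationship matrix per linkage group, computed from all
#' markers *not* on that group. Used as the polygenic covariance in the
#' association scan so the tested marker never contributes to its own
#' background.
#'
#' @param panel an imputed [marker_panel()] with at least two chromosomes.
#' @return named list of [kinship()] objects, one per chromosome, each with
#'   `meta$excluded_chromosome` set.
#' @export
loco_kinships <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  chroms <- unique(panel$map$chromosome)
  if (length(chroms) < 2) {
    stop_fatal("single-chromosome panel: use additive_relationship() instead")
  }
  out <- lapply(chroms, function(ch) {
    keep <- panel$map$marker_id[panel$map$chromosome != ch]
    additive_relationship(subset_panel(panel, markers = keep),
                          kind = "loco",
                          meta = list(excluded_chromosome = ch))
  })
  names(out) <- chroms
  out
}

#' QTL-masked additive relationship
#'
#' Additive relationship computed from all markers except those within
#' `window_cM` centimorgans of a detected QTL on the same chromosome. Keeps
#' large-effect regions out of the polygenic term when they are already
#' modeled explicitly.
#'
#' @param panel an imputed [marker_panel()].
#' @param qtl a [qtl_set()] (may be empty, in which case the full additive
#'   relationship is returned).
#' @param window_cM half-width of the mask around each QTL position.
#' @return a [kinship()] of kind `"additive_ab_masked"`; `meta$masked_windows`
#'   records the closed intervals removed per chromosome.
#' @export
qtl_masked_relationship <- function(panel, qtl, window_cM = 20) {
  stopifnot(inherits(panel, "marker_panel"))
  if (is.null(qtl) || nrow(qtl) == 0) {
    A <- additive_relationship(panel)
    return(kinship(A$values, kind = "additive_ab_masked",
                   meta = list(masked_windows = list())))
  }
  if (!all(qtl$marker_id %in% panel$marker_ids)) {
    stop_fatal("QTL marker(s) absent from the panel map")
  }
  windows <- lapply(seq_len(nrow(qtl)), function(i) {
    list(chromosome = qtl$chromosome[i],
         lo = qtl$position_cM[i] - window_cM,
         hi = qtl$position_cM[i] + window_cM)
  })
  masked <- rep(FALSE, panel$K)
  for (w in windows) {
    masked <- masked | (panel$map$chromosome == w$chromosome &
                          panel$map$position_cM >= w$lo &
                          panel$map$position_cM <= w$hi)
  }
  keep <- panel$map$marker_id[!masked]
  if (length(keep) == 0) stop_fatal("mask removes every marker")
  additive_relationship(subset_panel(panel, markers = keep),
                        kind = "additive_ab_masked",
                        meta = list(masked_windows = windows))
}
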