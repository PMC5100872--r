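#' Simulate a structured panel of inbred lines
#'
#' Balding-Nichols divergence model: ancestral allele frequencies are drawn
#' uniformly on (0.05, 0.95); each of `S` subpopulations draws its own
#' frequency per marker from `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, so
#' the expected fixation index among subpopulations is the target `fst`.
#' Lines are fully homozygous by default (dosage `2 * Bernoulli(p_s)`), the
#' regime of the diversity panels this emulates; an optional
#' heterozygosity rate converts a fraction of calls to dosage 1. Markers are
#' split evenly over chromosomes and placed uniformly on each map; panel-
#' monomorphic markers are resampled.
#'
#' @param sizes integer vector of subpopulation sizes (each >= 2).
#' @param fst target fixation index in (0, 1); values below 1e-8 give an
#'   unstructured panel.
#' @param n_markers total marker count.
#' @param n_chromosomes linkage groups.
#' @param chr_length_cM map length per chromosome.
#' @param het_rate fraction of calls set heterozygous (default 0, fully
#'   inbred).
#' @param seed RNG seed; same seed, same panel.
#' @return list with `panel` (a [marker_panel()]) and `assignment` (the true
#'   [subpop_assignment()]).
#' @export
simulate_panel <- function(sizes, fst, n_markers, n_chromosomes = 5L,
                           chr_length_cM = 100, het_rate = 0, seed = 1L) {
  stopifnot(all(sizes >= 2), fst >= 0, fst < 1, n_markers >= n_chromosomes)
  S <- length(sizes)
  n <- sum(sizes)
  grp <- rep(seq_len(S), sizes)

  with_seed(seed, {
    draw_block <- function(m) {
      p_anc <- stats::runif(m, 0.05, 0.95)
      ps <- if (fst < 1e-8) {
        matrix(rep(p_anc, each = S), nrow = S)
      } else {
        a <- p_anc * (1 - fst) / fst
        b <- (1 - p_anc) * (1 - fst) / fst
        matrix(stats::rbeta(S * m, rep(a, each = S), rep(b, each = S)),
               nrow = S)
      }
      # rows genotypes, cols markers; each line homozygous at p_{s,k}
      pr <- ps[grp, , drop = FALSE]
      matrix(2 * stats::rbinom(n * m, 1L, pr), nrow = n)
    }
    d <- draw_block(n_markers)
    for (round in 1:50) {
      mono <- colSums(d) %in% c(0, 2 * n)
      if (!any(mono)) break
      d[, mono] <- draw_block(sum(mono))
    }
    if (het_rate > 0) {
      flip <- matrix(stats::runif(n * n_markers) < het_rate, n, n_markers)
      d[flip] <- 1
    }
    rownames(d) <- sprintf("G%04d", seq_len(n))
    colnames(d) <- sprintf("M%05d", seq_len(n_markers))

    chr <- rep(seq_len(n_chromosomes), length.out = n_markers)
    chr <- sort(chr)
    pos <- unlist(lapply(seq_len(n_chromosomes), function(c_) {
      sort(stats::runif(sum(chr == c_), 0, chr_length_cM))
    }))
    map <- data.frame(marker_id = colnames(d),
                      chromosome = sprintf("chr%02d", chr),
                      position_cM = pos, stringsAsFactors = FALSE)
    panel <- marker_panel(d, map)
    assignment <- subpop_assignment(
      stats::setNames(sprintf("S%d", grp), rownames(d)))
    list(panel = panel, assignment = assignment)
  })
}

#' Simulate a trait with known genetic architecture
#'
#' Builds a genotypic value from `n_qtl` large-effect loci (drawn among
#' markers with minor allele frequency of at least 0.1 so each QTL actually
#' segregates) plus a polygenic background over all remaining markers, with
#' the QTL share of genetic variance fixed at `qtl_variance_fraction`;
#' Gaussian noise is added so the realized heritability
#' `var(g) / var(y)` matches the target up to the sampling error of the
#' noise draw. Returns the truth needed by power and recovery checks.
#'
#' @param panel an imputed [marker_panel()].
#' @param n_qtl number of large-effect loci (0 for a purely infinitesimal
#'   trait).
#' @param qtl_variance_fraction share of genetic variance carried by the
#'   QTL, in \[0, 1\].
#' @param h2 target heritability in (0, 1]; at 1 the phenotype equals the
#'   genotypic value.
#' @param seed RNG seed.
#' @param trait_name label for the resulting [trait_data()].
#' @return list with `trait` ([trait_data()]), `qtl_true` (a [qtl_set()]
#'   with an `effect` column), `genotypic_values` (named vector) and
#'   `realized_h2`.
#' @export
simulate_trait <- function(panel, n_qtl = 0L, qtl_variance_fraction = 0,
                           h2 = 0.7, seed = 1L, trait_name = "sim_trait") {
  stopifnot(inherits(panel, "marker_panel"),
            h2 > 0, h2 <= 1,
            qtl_variance_fraction >= 0, qtl_variance_fraction <= 1,
            n_qtl <= panel$K)
  if (qtl_variance_fraction == 1 && n_qtl == 0) {
    stop_fatal("qtl_variance_fraction = 1 requires at least one QTL")
  }
  f <- if (n_qtl == 0) 0 else qtl_variance_fraction
  d <- panel$dosage
  n <- nrow(d)

  with_seed(seed, {
    qtl_ids <- character(0)
    g_qtl <- rep(0, n)
    effects <- numeric(0)
    if (n_qtl > 0) {
      maf <- minor_allele_freq(panel)
      pool <- names(maf)[maf >= 0.1]
      if (length(pool) < n_qtl) pool <- names(maf)
      qtl_ids <- sample_exact(pool, n_qtl)
      effects <- stats::rnorm(n_qtl)
      g_qtl <- as.numeric(d[, qtl_ids, drop = FALSE] %*% effects)
    }
    bg_ids <- setdiff(colnames(d), qtl_ids)
    g_bg <- as.numeric(d[, bg_ids, drop = FALSE] %*%
                         stats::rnorm(length(bg_ids), 0, 1 / sqrt(length(bg_ids))))

    unit <- function(x) {
      s <- stats::sd(x)
      if (s == 0) stop_fatal("degenerate genetic signal (no variance)")
      (x - mean(x)) / s
    }
    g <- if (f == 0) unit(g_bg)
    else if (f == 1) unit(g_qtl)
    else sqrt(f) * unit(g_qtl) + sqrt(1 - f) * unit(g_bg)

    vg <- stats::var(g)
    e <- if (h2 < 1) stats::rnorm(n, 0, sqrt(vg * (1 - h2) / h2)) else rep(0, n)
    y <- g + e
    names(y) <- names(g) <- rownames(d)

    idx <- match(qtl_ids, panel$map$marker_id)
    qtl_true <- qtl_set(qtl_ids, panel$map$chromosome[idx],
                        panel$map$position_cM[idx],
                        rep(NA_real_, length(qtl_ids)))
    qtl_true$effect <- effects

    list(trait = trait_data(y, trait_name),
         qtl_true = qtl_true,
         genotypic_values = g,
         realized_h2 = vg / stats::var(y))
  })
}

#' Write a simulated data set with its truth sidecar
#'
#' Writes the standard panel/map/phenotype CSVs plus a `truth` CSV holding
#' the simulated genotypic values and QTL so downstream runs can score
#' recovery.
#'
#' @param sim output of [simulate_panel()].
#' @param trait_sim output of [simulate_trait()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, trait_sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_geno <- file.path(dir, "genotypes.csv")
  f_map <- file.path(dir, "map.csv")
  f_phen <- file.path(dir, "phenotypes.csv")
  f_truth <- file.path(dir, "truth_genotypic_values.csv")
  f_qtl <- file.path(dir, "truth_qtl.csv")
  f_subpop <- file.path(dir, "subpopulations.csv")
  write_panel(sim$panel, f_geno, f_map)
  data.table::fwrite(
    data.table::data.table(genotype_id = names(trait_sim$trait$values),
                           value = trait_sim$trait$values),
    f_phen, quote = FALSE)
  data.table::fwrite(
    data.table::data.table(genotype_id = names(trait_sim$genotypic_values),
                           genotypic_value = trait_sim$genotypic_values),
    f_truth, quote = FALSE)
  data.table::fwrite(as.data.frame(trait_sim$qtl_true), f_qtl, quote = FALSE)
  data.table::fwrite(
    data.table::data.table(genotype_id = names(sim$assignment$groups),
                           subpopulation = sim$assignment$groups),
    f_subpop, quote = FALSE)
  invisible(c(f_geno, f_map, f_phen, f_truth, f_qtl, f_subpop))
}
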