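#' Marker panel
#'
#' A `marker_panel` holds a genotype-by-marker allele-dosage matrix (values
#' 0, 1, 2 counting copies of one of the two alleles, `NA` for missing calls)
#' together with a genetic map giving each marker's linkage group and
#' centimorgan position. All relationship matrices, scans and samplers in the
#' package consume this one canonical coding; the 0/0.5/1 scores used by the
#' identity-by-state matrix are obtained internally by the fixed rescaling
#' dosage/2 and never stored.
#'
#' Markers are sorted by (chromosome, position) at construction so map order
#' is always consistent with matrix column order.
#'
#' @param dosage numeric matrix, genotypes in rows, markers in columns, with
#'   rownames (genotype ids) and colnames (marker ids). Values must be 0, 1,
#'   2 or `NA`.
#' @param map data.frame with columns `marker_id`, `chromosome`,
#'   `position_cM` (non-negative centimorgans); one row per dosage column.
#' @return an object of class `marker_panel` with elements `dosage`, `map`,
#'   `genotype_ids`, `marker_ids`, and marker count `K`.
#' @export
marker_panel <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop_fatal("dosage matrix must carry genotype rownames and marker colnames")
  }
  if (anyDuplicated(rownames(dosage))) stop_fatal("duplicate genotype ids")
  if (anyDuplicated(colnames(dosage))) stop_fatal("duplicate marker ids")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop_fatal("dosage values must be 0, 1, 2 or NA")

  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "position_cM")
  if (!all(need %in% names(map))) {
    stop_fatal("map must have columns: ", paste(need, collapse = ", "))
  }
  map <- map[, need]
  map$marker_id <- as.character(map$marker_id)
  map$chromosome <- as.character(map$chromosome)
  map$position_cM <- as.numeric(map$position_cM)
  if (anyDuplicated(map$marker_id)) stop_fatal("duplicate marker ids in map")
  missing_map <- setdiff(colnames(dosage), map$marker_id)
  if (length(missing_map)) {
    stop_fatal("markers absent from map: ", paste(utils::head(missing_map, 5), collapse = ", "))
  }
  map <- map[match(colnames(dosage), map$marker_id), ]
  if (any(!is.finite(map$position_cM)) || any(map$position_cM < 0)) {
    stop_fatal("map positions must be finite, non-negative centimorgans")
  }

  ord <- order(map$chromosome, map$position_cM)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosage <- dosage[, map$marker_id, drop = FALSE]

  structure(
    list(
      dosage = dosage,
      map = map,
      genotype_ids = rownames(dosage),
      marker_ids = colnames(dosage),
      K = ncol(dosage)
    ),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf(
    "marker_panel: %d genotypes x %d markers on %d linkage group(s); %d missing call(s)\n",
    nrow(x$dosage), x$K, length(unique(x$map$chromosome)), sum(is.na(x$dosage))
  ))
  invisible(x)
}

#' Subset a marker panel
#'
#' @param panel a [marker_panel()].
#' @param genotypes,markers character vectors of ids (or logical/integer
#'   indices) to keep; `NULL` keeps all.
#' @return a `marker_panel`.
#' @export
subset_panel <- function(panel, genotypes = NULL, markers = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  d <- panel$dosage
  if (!is.null(genotypes)) d <- d[genotypes, , drop = FALSE]
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  marker_panel(d, panel$map[panel$map$marker_id %in% colnames(d), ])
}

#' Per-marker allele frequency
#'
#' Frequency of the counted allele, computed on observed (non-missing) calls
#' only, so imputation can never manufacture polymorphism.
#'
#' @param panel a [marker_panel()].
#' @return named numeric vector of frequencies in \[0, 1\].
#' @export
allele_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}

#' Minor allele frequency per marker
#' @param panel a [marker_panel()].
#' @return named numeric vector, `pmin(p, 1 - p)`.
#' @export
minor_allele_freq <- function(panel) {
  p <- allele_freq(panel)
  pmin(p, 1 - p)
}

#' Read a genotype panel from disk
#'
#' Two dialects are supported. `csv`: first column genotype id, remaining
#' columns marker dosages, plus a sidecar map CSV with columns
#' `marker_id, chromosome, position_cM`. `plink_raw`: the PLINK `.raw`
#' additive export (`FID IID PAT MAT SEX PHENOTYPE <marker>_<allele> ...`),
#' whitespace-separated, with the same sidecar map; the `_<allele>` suffix is
#' stripped from marker names. Any cell that is not 0, 1 or 2 becomes a
#' missing call.
#'
#' @param path genotype file.
#' @param map_path map CSV.
#' @param format `"csv"` or `"plink_raw"`.
#' @return a [marker_panel()].
#' @seealso [write_panel()] for the exact inverse.
#' @export
load_panel <- function(path, map_path, format = c("csv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fatal("genotype file not found: ", path)
  if (!file.exists(map_path)) stop_fatal("map file not found: ", map_path)

  if (format == "csv") {
    dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", ""))
    ids <- as.character(dt[[1]])
    dt <- dt[, -1]
  } else {
    dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", ""))
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(fixed %in% names(dt))) {
      stop_fatal("plink_raw file lacks the standard header columns")
    }
    ids <- as.character(dt[["IID"]])
    dt <- dt[, setdiff(names(dt), fixed), with = FALSE]
    names(dt) <- sub("_[^_]*$", "", names(dt))
  }
  if (anyDuplicated(ids)) stop_fatal("duplicate genotype ids in ", path)
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(dt)), nrow = length(ids),
           dimnames = list(ids, names(dt)))
  )
  mat[!(mat %in% c(0, 1, 2))] <- NA_real_

  map <- data.table::fread(map_path, header = TRUE)
  map <- as.data.frame(map)
  marker_panel(mat, map)
}

#' Write a genotype panel to disk
#'
#' Writes the genotype CSV and map CSV consumed by [load_panel()];
#' `load_panel(write_panel(...))` reproduces the panel exactly.
#'
#' @param panel a [marker_panel()].
#' @param path,map_path output files.
#' @return invisibly, `c(path, map_path)`.
#' @export
write_panel <- function(panel, path, map_path) {
  stopifnot(inherits(panel, "marker_panel"))
  dt <- data.table::data.table(genotype_id = panel$genotype_ids)
  dt <- cbind(dt, data.table::as.data.table(panel$dosage))
  data.table::fwrite(dt, path, na = "NA", quote = FALSE)
  data.table::fwrite(panel$map, map_path, quote = FALSE)
  invisible(c(path, map_path))
}

#' Trait data: adjusted means per genotype
#'
#' @param values named numeric vector, one adjusted-mean phenotype per
#'   genotype; all values finite.
#' @param trait_name label.
#' @return an object of class `trait_data`.
#' @export
trait_data <- function(values, trait_name = "trait") {
  if (is.null(names(values))) stop_fatal("trait values must be named by genotype id")
  if (anyDuplicated(names(values))) stop_fatal("duplicate genotype ids in trait")
  values <- values[!is.na(values)]
  if (any(!is.finite(values))) stop_fatal("trait values must be finite")
  structure(list(trait_name = trait_name, values = values), class = "trait_data")
}

#' @export
print.trait_data <- function(x, ...) {
  cat(sprintf("trait_data '%s': %d genotypes, mean %.4g, sd %.4g\n",
              x$trait_name, length(x$values), mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Read phenotype tables
#'
#' Expects a CSV whose first column is the genotype id and whose remaining
#' numeric columns are adjusted means, one trait per column.
#'
#' @param path phenotype CSV.
#' @return named list of [trait_data()] objects, one per trait column.
#' @export
load_traits <- function(path) {
  if (!file.exists(path)) stop_fatal("phenotype file not found: ", path)
  dt <- as.data.frame(data.table::fread(path, header = TRUE))
  ids <- as.character(dt[[1]])
  out <- lapply(names(dt)[-1], function(tr) {
    v <- as.numeric(dt[[tr]])
    names(v) <- ids
    trait_data(v, tr)
  })
  names(out) <- names(dt)[-1]
  out
}

#' Filter a marker panel
#'
#' Applies the quality rules in the order they act on the real panels:
#' genotype filters first (missing-call rate, then heterozygosity), then
#' marker filters (missing rate, monomorphic, minor allele frequency).
#' Each rule's removal count is reported against the panel state at the time
#' the rule ran, so counts are sequential, not marginal.
#'
#' @param panel a [marker_panel()].
#' @param max_geno_missing drop genotypes with missing-call rate above this.
#' @param max_geno_het drop genotypes with heterozygosity above this
#'   (fraction of observed calls equal to 1).
#' @param max_marker_missing drop markers with missing rate above this.
#' @param maf_min drop markers with minor allele frequency below this,
#'   computed on observed calls of the surviving genotypes.
#' @param drop_monomorphic drop markers with a single observed allele.
#' @return list with elements `panel` (the filtered [marker_panel()]) and
#'   `report` (a `filter_report`).
#' @export
filter_panel <- function(panel,
                         max_geno_missing = 0.10,
                         max_geno_het = 0.05,
                         max_marker_missing = 0.10,
                         maf_min = 0.05,
                         drop_monomorphic = TRUE) {
  stopifnot(inherits(panel, "marker_panel"))
  thr <- c(max_geno_missing, max_geno_het, max_marker_missing, maf_min)
  if (any(thr < 0 | thr > 1)) stop_fatal("thresholds must lie in [0, 1]")

  d <- panel$dosage
  n_geno_in <- nrow(d)
  n_marker_in <- ncol(d)

  miss_rate <- rowMeans(is.na(d))
  drop_miss <- miss_rate > max_geno_missing
  d <- d[!drop_miss, , drop = FALSE]

  het_rate <- rowMeans(d == 1, na.rm = TRUE)
  het_rate[is.nan(het_rate)] <- 0
  drop_het <- het_rate > max_geno_het
  d <- d[!drop_het, , drop = FALSE]
  if (nrow(d) == 0) stop_fatal("all genotypes removed by genotype filters")

  mk_miss <- colMeans(is.na(d))
  drop_mkmiss <- mk_miss > max_marker_missing
  d <- d[, !drop_mkmiss, drop = FALSE]

  if (drop_monomorphic && ncol(d)) {
    p <- colMeans(d, na.rm = TRUE) / 2
    mono <- is.nan(p) | p == 0 | p == 1
  } else {
    mono <- rep(FALSE, ncol(d))
  }
  d <- d[, !mono, drop = FALSE]

  if (ncol(d)) {
    p <- colMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    low_maf <- maf < maf_min
  } else {
    low_maf <- logical(0)
  }
  d <- d[, !low_maf, drop = FALSE]

  report <- structure(
    list(
      n_genotypes_in = n_geno_in,
      n_genotypes_out = nrow(d),
      n_markers_in = n_marker_in,
      n_markers_out = ncol(d),
      removed_genotypes = c(missing_rate = sum(drop_miss),
                            heterozygosity = sum(drop_het)),
      removed_markers = c(missing_rate = sum(drop_mkmiss),
                          monomorphic = sum(mono),
                          maf = sum(low_maf))
    ),
    class = "filter_report"
  )
  if (ncol(d) == 0) {
    stop_fatal("all markers removed by filtering (",
               paste(names(report$removed_markers), report$removed_markers,
                     sep = "=", collapse = ", "), ")")
  }
  out <- marker_panel(d, panel$map[panel$map$marker_id %in% colnames(d), ])
  list(panel = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  cat(sprintf("  genotypes: %d -> %d (missing-rate %d, heterozygosity %d)\n",
              x$n_genotypes_in, x$n_genotypes_out,
              x$removed_genotypes[["missing_rate"]],
              x$removed_genotypes[["heterozygosity"]]))
  cat(sprintf("  markers:   %d -> %d (missing-rate %d, monomorphic %d, MAF %d)\n",
              x$n_markers_in, x$n_markers_out,
              x$removed_markers[["missing_rate"]],
              x$removed_markers[["monomorphic"]],
              x$removed_markers[["maf"]]))
  invisible(x)
}

#' Impute missing marker calls
#'
#' Frequency-based single-marker imputation. `expected_dosage` fills each
#' missing call with `round(2 * p_hat)` where `p_hat` is the marker's allele
#' frequency on observed calls; `bernoulli_draw` samples
#' `2 * Bernoulli(p_hat)`, the inbred-line convention where a missing call is
#' one of the two homozygotes.
#'
#' @param panel a [marker_panel()].
#' @param mode `"expected_dosage"` or `"bernoulli_draw"`.
#' @param seed RNG seed for `bernoulli_draw`; same seed, same fill.
#' @return a [marker_panel()] with no missing entries.
#' @export
impute_missing <- function(panel, mode = c("expected_dosage", "bernoulli_draw"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "marker_panel"))
  d <- panel$dosage
  if (!anyNA(d)) return(panel)

  obs <- colSums(!is.na(d))
  if (any(obs == 0)) {
    stop_fatal("marker(s) fully missing (filter first): ",
               paste(utils::head(colnames(d)[obs == 0], 5), collapse = ", "))
  }
  p <- colMeans(d, na.rm = TRUE) / 2
  na_idx <- which(is.na(d), arr.ind = TRUE)
  pk <- p[na_idx[, 2]]
  if (mode == "expected_dosage") {
    fill <- pmin(2, pmax(0, round(2 * pk)))
  } else {
    fill <- with_seed(seed, 2 * stats::rbinom(length(pk), 1L, pk))
  }
  d[na_idx] <- fill
  marker_panel(d, panel$map)
}
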