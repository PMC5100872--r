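#' Predictive ability
#'
#' Pearson correlation between observed and predicted phenotypes over the
#' given genotypes (the validation set by default). Undefined correlations
#' (fewer than 3 complete pairs, or zero variance on either side) are
#' recorded as `NA`, never as 0.
#'
#' @param pred a `prediction_result`.
#' @param trait a [trait_data()].
#' @param ids genotypes to correlate over.
#' @return Pearson r, or `NA`.
#' @export
predictive_ability <- function(pred, trait, ids) {
  obs <- trait$values[intersect(ids, names(trait$values))]
  prd <- pred$predictions[names(obs)]
  ok <- is.finite(obs) & is.finite(prd)
  if (sum(ok) < 3) return(NA_real_)
  obs <- obs[ok]; prd <- prd[ok]
  if (stats::var(obs) == 0 || stats::var(prd) == 0) return(NA_real_)
  stats::cor(obs, prd)
}

#' Aggregate correlations on the Fisher-z scale
#'
#' Correlations are variance-stabilized with `z = atanh(r)`, averaged, and
#' back-transformed with `tanh`; the standard error is reported on the z
#' scale (`sd(z) / sqrt(m)`). Missing or boundary (|r| >= 1) values are
#' dropped and counted.
#'
#' @param r_values vector of Pearson correlations.
#' @return list with `mean_r`, `se_z`, `n_used`, `n_dropped`.
#' @export
fisher_aggregate <- function(r_values) {
  r <- r_values[is.finite(r_values) & abs(r_values) < 1]
  n_dropped <- length(r_values) - length(r)
  if (!length(r)) {
    return(list(mean_r = NA_real_, se_z = NA_real_, n_used = 0L,
                n_dropped = n_dropped))
  }
  z <- atanh(r)
  se <- if (length(z) >= 2) stats::sd(z) / sqrt(length(z)) else NA_real_
  list(mean_r = tanh(mean(z)), se_z = se, n_used = length(z),
       n_dropped = n_dropped)
}

#' Predictive ability within subpopulations
#'
#' [predictive_ability()] restricted to each subpopulation's validation
#' members. Groups with fewer than 3 validation genotypes are reported `NA`
#' with a small-group flag, since no reliable estimate is possible there.
#'
#' @param pred a `prediction_result`.
#' @param trait a [trait_data()].
#' @param split a [training_split()].
#' @param assignment a [subpop_assignment()] covering the validation ids.
#' @return data.frame `subpopulation, n_validation, r, small_group`.
#' @export
within_subpop_ability <- function(pred, trait, split, assignment) {
  groups <- names(assignment$sizes)
  g <- assignment$groups[split$validation_ids]
  out <- lapply(groups, function(s) {
    ids <- split$validation_ids[g == s & !is.na(g)]
    small <- length(ids) < 3
    data.frame(subpopulation = s, n_validation = length(ids),
               r = if (small) NA_real_ else predictive_ability(pred, trait, ids),
               small_group = small, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run a full method x model x size experiment
#'
#' Orchestrates the whole benchmark on one calibration panel: for every
#' combination of trait, training-set construction method, prediction model
#' and training-set size, it draws `n_realizations` independent splits
#' (realization `i` uses seed `seed + i` so any cell can be re-run in
#' isolation), detects QTL on the training set when the model needs them
#' (scan + multiple-testing threshold + peak collapsing, never touching the
#' validation set), fits the model, computes validation predictive ability,
#' and aggregates on the Fisher-z scale.
#'
#' @param panel an imputed [marker_panel()] (the calibration set).
#' @param traits named list of [trait_data()] objects.
#' @param methods subset of `c("U", "SU", "CD", "S", "R")`.
#' @param models subset of `c("QTL", "GBLUP", "QGBLUP", "RKHS")`.
#' @param sizes training-set sizes.
#' @param n_realizations independent splits per cell.
#' @param h2 heritability used for the CD criterion's variance ratio (a
#'   single value or one per trait).
#' @param assignment a [subpop_assignment()]; inferred via
#'   [characterize_structure()] when `NULL` (needed by SU/S and the
#'   within-subpopulation breakdown).
#' @param seed base seed.
#' @param gwas_alpha genome-wide significance level for QTL detection.
#' @param theta_grid RKHS bandwidth grid.
#' @param within_subpop also compute the per-subpopulation ability table.
#' @param verbose print per-cell progress.
#' @return object of class `ability_summary`: `summary` (one row per cell
#'   with Fisher-z mean r, z-scale SE and realization count), `raw` (one row
#'   per realization), optional `within` (per-subpopulation aggregate), and
#'   `failures` (cells that errored, recorded and skipped).
#' @export
run_experiment <- function(panel, traits, methods = c("U", "SU", "CD", "S", "R"),
                           models = "GBLUP", sizes, n_realizations = 100L,
                           h2 = 0.85, assignment = NULL, seed = 1L,
                           gwas_alpha = 0.01,
                           theta_grid = c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 5),
                           within_subpop = FALSE, verbose = FALSE) {
  stopifnot(inherits(panel, "marker_panel"))
  if (inherits(traits, "trait_data")) traits <- list(traits)
  if (is.null(names(traits))) {
    names(traits) <- vapply(traits, `[[`, "", "trait_name")
  }
  methods <- match.arg(methods, c("U", "SU", "CD", "S", "R"), several.ok = TRUE)
  models <- match.arg(models, c("QTL", "GBLUP", "QGBLUP", "RKHS"),
                      several.ok = TRUE)
  if (length(h2) == 1) h2 <- stats::setNames(rep(h2, length(traits)), names(traits))

  K_ibs <- ibs_matrix(panel)
  A <- additive_relationship(panel)
  need_structure <- is.null(assignment) &&
    (any(c("SU", "S") %in% methods) || within_subpop)
  if (need_structure) {
    assignment <- characterize_structure(panel, seed = seed)$assignment
  }
  need_qtl <- any(c("QTL", "QGBLUP") %in% models)
  loco <- if (need_qtl) loco_kinships(panel) else NULL

  # radii are a property of (panel, size, discard rule), shared by realizations
  radii_u <- radii_su <- list()
  for (sz in sizes) {
    if ("U" %in% methods) radii_u[[as.character(sz)]] <-
        find_radius(K_ibs, sz)
    if ("SU" %in% methods) radii_su[[as.character(sz)]] <-
        find_radius(K_ibs, sz, strata = assignment)
  }

  raw <- list()
  within <- list()
  failures <- list()
  splits_store <- list()

  for (tr_name in names(traits)) {
    trait <- traits[[tr_name]]
    lam <- lambda_from_h2(h2[[tr_name]])
    for (sz in sizes) {
      for (method in methods) {
        for (i in seq_len(n_realizations)) {
          s_i <- seed + i
          cell <- sprintf("%s/%s/size %d/realization %d", tr_name, method, sz, i)
          split <- tryCatch(switch(
            method,
            U = sample_uniform(K_ibs, sz, seed = s_i,
                               r = radii_u[[as.character(sz)]]),
            SU = sample_uniform(K_ibs, sz, seed = s_i, strata = assignment,
                                r = radii_su[[as.character(sz)]]),
            CD = sample_cd(A, sz, lambda = lam, seed = s_i),
            S = sample_stratified(assignment, sz, seed = s_i),
            R = sample_random(panel$genotype_ids, sz, seed = s_i)
          ), error = function(e) e)
          if (inherits(split, "error")) {
            failures[[length(failures) + 1L]] <- data.frame(
              cell = cell, stage = "split", message = conditionMessage(split))
            next
          }
          key <- sprintf("%s|%d|%s", tr_name, sz, method)
          splits_store[[key]] <- c(splits_store[[key]], list(split))

          qtl <- NULL
          if (need_qtl) {
            qtl <- tryCatch({
              scan <- gwas_scan(panel, trait, loco, split$training_ids)
              thr <- li_ji_threshold(panel, gwas_alpha, split$training_ids)
              select_qtl(scan, thr)
            }, error = function(e) e)
            if (inherits(qtl, "error")) {
              failures[[length(failures) + 1L]] <- data.frame(
                cell = cell, stage = "gwas", message = conditionMessage(qtl))
              next
            }
          }
          for (model in models) {
            fit <- tryCatch(
              fit_prediction_model(model, trait, panel, split$training_ids,
                                   qtl = qtl, A = A, theta_grid = theta_grid,
                                   seed = s_i),
              error = function(e) e)
            if (inherits(fit, "error")) {
              failures[[length(failures) + 1L]] <- data.frame(
                cell = paste0(cell, "/", model), stage = "fit",
                message = conditionMessage(fit))
              next
            }
            r <- predictive_ability(fit, trait, split$validation_ids)
            raw[[length(raw) + 1L]] <- data.frame(
              trait = tr_name, method = method, model = model, size = sz,
              realization = i, r = r, stringsAsFactors = FALSE)
            if (within_subpop && !is.null(assignment)) {
              w <- within_subpop_ability(fit, trait, split, assignment)
              w$trait <- tr_name; w$method <- method; w$model <- model
              w$size <- sz; w$realization <- i
              within[[length(within) + 1L]] <- w
            }
          }
        }
        if (verbose) {
          message(sprintf("done %s / %s / size %d", tr_name, method, sz))
        }
      }
    }
  }

  raw <- if (length(raw)) do.call(rbind, raw) else
    data.frame(trait = character(0), method = character(0),
               model = character(0), size = integer(0),
               realization = integer(0), r = numeric(0))
  cells <- unique(raw[, c("trait", "method", "model", "size")])
  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sel <- raw$trait == cells$trait[k] & raw$method == cells$method[k] &
      raw$model == cells$model[k] & raw$size == cells$size[k]
    agg <- fisher_aggregate(raw$r[sel])
    cbind(cells[k, , drop = FALSE],
          data.frame(mean_r = agg$mean_r, se_z = agg$se_z,
                     n_realizations = agg$n_used))
  }))
  rownames(summary) <- NULL

  within_summary <- NULL
  if (length(within)) {
    wall <- do.call(rbind, within)
    wcells <- unique(wall[, c("trait", "method", "model", "size", "subpopulation")])
    within_summary <- do.call(rbind, lapply(seq_len(nrow(wcells)), function(k) {
      sel <- wall$trait == wcells$trait[k] & wall$method == wcells$method[k] &
        wall$model == wcells$model[k] & wall$size == wcells$size[k] &
        wall$subpopulation == wcells$subpopulation[k]
      agg <- fisher_aggregate(wall$r[sel])
      cbind(wcells[k, , drop = FALSE],
            data.frame(mean_r = agg$mean_r, se_z = agg$se_z,
                       n_realizations = agg$n_used))
    }))
    rownames(within_summary) <- NULL
  }

  structure(
    list(summary = summary, raw = raw, within = within_summary,
         splits = splits_store,
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         assignment = assignment, seed = seed),
    class = "ability_summary"
  )
}

#' @export
print.ability_summary <- function(x, ...) {
  cat("ability_summary (Fisher-z aggregated predictive ability)\n")
  print(x$summary, digits = 3)
  if (!is.null(x$failures)) {
    cat(sprintf("%d cell failure(s) recorded\n", nrow(x$failures)))
  }
  invisible(x)
}
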