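#' Mixed-model specification
#'
#' Bundles the training phenotypes, fixed-effect design, genotype incidence
#' and random-effect kernels consumed by [reml_fit()] and [predict_blup()].
#' Kernels are relationship matrices over the full calibration set; records
#' are matched to calibration genotypes by name, so the record-level
#' covariance of term `j` is `K_j[train, train]`.
#'
#' @param trait a [trait_data()].
#' @param training_ids genotypes whose phenotypes enter the model.
#' @param kernels named list of [kinship()] objects or plain symmetric
#'   matrices over the calibration set (all sharing the same ids).
#' @param X fixed-effect design over training records; defaults to an
#'   intercept-only column of ones.
#' @return object of class `mm_spec`.
#' @export
mm_spec <- function(trait, training_ids, kernels, X = NULL) {
  stopifnot(inherits(trait, "trait_data"), length(kernels) >= 1)
  kernels <- lapply(kernels, function(k) if (inherits(k, "kinship")) k$values else k)
  if (is.null(names(kernels))) names(kernels) <- paste0("g", seq_along(kernels))
  ids_all <- rownames(kernels[[1]])
  for (k in kernels) {
    if (!identical(rownames(k), ids_all)) stop_fatal("kernels disagree on ids")
  }
  training_ids <- intersect(training_ids, names(trait$values))
  training_ids <- intersect(training_ids, ids_all)
  y <- trait$values[training_ids]
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(training_ids, "mu"))
  if (nrow(X) != n) stop_fatal("X rows must match training records")
  if (qr(X)$rank < ncol(X)) stop_fatal("X is not full column rank")
  structure(
    list(y = y, X = X, training_ids = training_ids, ids_all = ids_all,
         kernels = kernels),
    class = "mm_spec"
  )
}

# Record-level covariance of kernel j (one record per training genotype).
record_kernel <- function(spec, j) {
  spec$kernels[[j]][spec$training_ids, spec$training_ids, drop = FALSE]
}

#' Restricted log-likelihood profile over the variance ratio
#'
#' Evaluates the single-kernel restricted log-likelihood at given values of
#' `delta = sigma_e^2 / sigma_g^2`, profiling out the genetic variance and
#' fixed effects. Used by the spectral REML path and available as an
#' independent check of the optimizer.
#'
#' @param spec a single-kernel [mm_spec()].
#' @param ratios values of the residual/genetic variance ratio.
#' @return numeric vector of restricted log-likelihoods.
#' @export
reml_profile <- function(spec, ratios) {
  stopifnot(inherits(spec, "mm_spec"), length(spec$kernels) == 1)
  eg <- eigen(record_kernel(spec, 1), symmetric = TRUE)
  vapply(ratios, function(d) reml_ll_delta(spec, eg, d)$ll, numeric(1))
}

# Profiled restricted log-likelihood at ratio delta, via the spectral
# decomposition eg of the record-level kernel.
reml_ll_delta <- function(spec, eg, delta) {
  n <- length(spec$y)
  p <- ncol(spec$X)
  dd <- pmax(eg$values, 0) + delta
  if (any(dd <= 0)) return(list(ll = -Inf))
  Ut_y <- crossprod(eg$vectors, spec$y)
  Ut_X <- crossprod(eg$vectors, spec$X)
  XtVX <- crossprod(Ut_X, Ut_X / dd)
  XtVy <- crossprod(Ut_X, Ut_y / dd)
  beta <- solve(XtVX, XtVy)
  r <- Ut_y - Ut_X %*% beta
  rss <- sum(r^2 / dd)
  s2g <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2g) + (n - p) +
                  sum(log(dd)) + determinant(XtVX, logarithm = TRUE)$modulus)
  list(ll = as.numeric(ll), s2g = s2g, beta = beta)
}

#' Variance components
#'
#' Printed container returned by [reml_fit()]: one genetic variance per
#' random term, the residual variance, the derived ratio
#' `lambda = sigma_e^2 / sigma_g^2` (first term), the restricted
#' log-likelihood and convergence/degeneracy flags.
#' @name variance_components
NULL

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components\n")
  for (nm in names(x$sigma2)) cat(sprintf("  sigma2[%s] = %.6g\n", nm, x$sigma2[[nm]]))
  cat(sprintf("  sigma2_e  = %.6g\n  lambda    = %.6g\n  logLik(R) = %.4f\n",
              x$sigma2_e, x$lambda, x$loglik))
  if (!x$converged) cat("  [not converged]\n")
  if (x$degenerate) cat("  [degenerate: terms unidentifiable]\n")
  invisible(x)
}

#' REML fit of a genomic mixed model
#'
#' Single-kernel models are solved by spectral decomposition of the
#' record-level kernel and 1-D optimization of the profiled restricted
#' likelihood over the variance ratio (tolerance 1e-8 on the ratio).
#' Multi-kernel models use the fixed-point (EM-type) REML iteration
#' `sigma_j^2 <- sigma_j^2 * (y' P H_j P y) / tr(P H_j)` with at most
#' `max_iter` iterations and a relative-change tolerance of 1e-6.
#' Non-convergence flags the result rather than failing; a kernel that is
#' numerically a multiple of the identity makes the genetic and residual
#' variances unidentifiable and sets the `degenerate` flag.
#'
#' @param spec an [mm_spec()].
#' @param max_iter iteration cap for the multi-kernel path.
#' @return an object of class `variance_components`.
#' @export
reml_fit <- function(spec, max_iter = 500L) {
  stopifnot(inherits(spec, "mm_spec"))
  m <- length(spec$kernels)
  if (m == 1L) reml_fit_single(spec) else reml_fit_multi(spec, max_iter)
}

reml_fit_single <- function(spec) {
  H <- record_kernel(spec, 1)
  n <- length(spec$y)
  dH <- mean(diag(H))
  degenerate <- max(abs(H - diag(dH, n))) < 1e-8 * max(dH, 1)
  eg <- eigen(H, symmetric = TRUE)
  obj <- function(logd) reml_ll_delta(spec, eg, exp(logd))$ll
  opt <- stats::optimize(obj, interval = c(log(1e-8), log(1e8)),
                         maximum = TRUE, tol = 1e-10)
  delta <- exp(opt$maximum)
  fit <- reml_ll_delta(spec, eg, delta)
  s2g <- fit$s2g
  s2e <- delta * s2g
  structure(
    list(sigma2 = stats::setNames(s2g, names(spec$kernels)[1]),
         sigma2_e = s2e, lambda = delta, loglik = fit$ll,
         converged = TRUE, degenerate = degenerate),
    class = "variance_components"
  )
}

reml_fit_multi <- function(spec, max_iter = 500L, tol = 1e-6) {
  y <- spec$y
  X <- spec$X
  n <- length(y)
  m <- length(spec$kernels)
  H <- lapply(seq_len(m), function(j) record_kernel(spec, j))
  # identical kernels cannot be separated
  degenerate <- FALSE
  if (m > 1) {
    for (j in 2:m) {
      if (max(abs(H[[j]] - H[[1]])) < 1e-10 * max(abs(H[[1]]), 1)) degenerate <- TRUE
    }
  }
  vy <- stats::var(y)
  s2 <- rep(vy / (m + 1), m)
  s2e <- vy / (m + 1)
  converged <- FALSE
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    V <- diag(s2e, n)
    for (j in seq_len(m)) V <- V + s2[j] * H[[j]]
    Vc <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-8 * vy, n)))
    Vinv <- chol2inv(Vc)
    VX <- Vinv %*% X
    P <- Vinv - VX %*% solve(crossprod(X, VX), t(VX))
    Py <- P %*% y
    s2_new <- vapply(seq_len(m), function(j) {
      trPH <- sum(P * H[[j]])                       # tr(P H_j), H symmetric
      if (trPH <= 0) return(s2[j])
      s2[j] * as.numeric(crossprod(Py, H[[j]] %*% Py)) / trPH
    }, numeric(1))
    s2e_new <- s2e * as.numeric(crossprod(Py)) / sum(diag(P))
    rel <- max(abs(c(s2_new - s2, s2e_new - s2e))) / max(vy, 1e-12)
    s2 <- pmax(s2_new, 0)
    s2e <- max(s2e_new, 1e-12 * vy)
    if (rel < tol) { converged <- TRUE; break }
  }
  V <- diag(s2e, n)
  for (j in seq_len(m)) V <- V + s2[j] * H[[j]]
  Vc <- chol(V + diag(1e-10 * vy, n))
  Vinv <- chol2inv(Vc)
  VX <- Vinv %*% X
  XtVX <- crossprod(X, VX)
  beta <- solve(XtVX, crossprod(VX, y))
  r <- y - X %*% beta
  ll <- -0.5 * (2 * sum(log(diag(Vc))) +
                  determinant(XtVX, logarithm = TRUE)$modulus +
                  as.numeric(crossprod(r, Vinv %*% r)) +
                  (n - ncol(X)) * log(2 * pi))
  structure(
    list(sigma2 = stats::setNames(s2, names(spec$kernels)),
         sigma2_e = s2e,
         lambda = if (s2[1] > 0) s2e / s2[1] else Inf,
         loglik = as.numeric(ll), converged = converged,
         degenerate = degenerate),
    class = "variance_components"
  )
}

#' BLUP of genotypic values for all calibration genotypes
#'
#' Given fitted variance components, estimates fixed effects by generalized
#' least squares and the genotypic value of every calibration genotype
#' (training and validation) by the conditional expectation
#' `g_hat = sum_j sigma_j^2 K_j[, train] V^{-1} (y - X beta_hat)`.
#' Predictions are `beta_hat[intercept] + g_hat`.
#'
#' @param spec the [mm_spec()] the components were fitted on.
#' @param vc a `variance_components` object from [reml_fit()].
#' @param model label stored on the result.
#' @return object of class `prediction_result` with named `predictions`
#'   covering every calibration genotype, the `vc`, and the model label.
#' @export
predict_blup <- function(spec, vc, model = "GBLUP") {
  stopifnot(inherits(spec, "mm_spec"), inherits(vc, "variance_components"))
  y <- spec$y
  n <- length(y)
  m <- length(spec$kernels)
  V <- diag(vc$sigma2_e, n)
  for (j in seq_len(m)) V <- V + vc$sigma2[[j]] * record_kernel(spec, j)
  Vc <- tryCatch(chol(V), error = function(e) {
    chol(V + diag(1e-8 * max(diag(V)), n))
  })
  Vinv <- chol2inv(Vc)
  VX <- Vinv %*% spec$X
  beta <- solve(crossprod(spec$X, VX), crossprod(VX, y))
  w <- Vinv %*% (y - spec$X %*% beta)
  ghat <- rep(0, length(spec$ids_all))
  names(ghat) <- spec$ids_all
  for (j in seq_len(m)) {
    Kj <- spec$kernels[[j]][, spec$training_ids, drop = FALSE]
    ghat <- ghat + vc$sigma2[[j]] * as.numeric(Kj %*% w)
  }
  preds <- beta[1] + ghat
  structure(
    list(model = model, predictions = preds, genetic_values = ghat,
         beta = as.numeric(beta), vc = vc, theta = NULL, qtl = NULL),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result [%s]: %d genotypes", x$model,
              length(x$predictions)))
  if (!is.null(x$theta)) cat(sprintf(", theta = %g", x$theta))
  if (!is.null(x$qtl)) cat(sprintf(", %d QTL", nrow(x$qtl)))
  cat("\n")
  invisible(x)
}

#' QTL set
#'
#' Markers retained as QTL after an association scan: id, linkage group, map
#' position and the p-value at detection (`NA` for externally forced loci).
#'
#' @param marker_id,chromosome,position_cM,p_value parallel vectors.
#' @return data.frame of class `qtl_set`.
#' @export
qtl_set <- function(marker_id = character(0), chromosome = character(0),
                    position_cM = numeric(0), p_value = numeric(0)) {
  out <- data.frame(marker_id = as.character(marker_id),
                    chromosome = as.character(chromosome),
                    position_cM = as.numeric(position_cM),
                    p_value = as.numeric(p_value),
                    stringsAsFactors = FALSE)
  class(out) <- c("qtl_set", "data.frame")
  out
}

#' Genome-wide association scan with LOCO polygenic control
#'
#' For each chromosome, the null model `y = mu + G + e` with
#' `G ~ N(0, sigma_g^2 A_loco)` (the leave-one-chromosome-out kinship) is
#' fitted once by REML; its variance components are then fixed and every
#' marker on that chromosome is tested as a fixed effect by a generalized
#' least squares Wald chi-square test with 1 degree of freedom. Markers
#' monomorphic within the training set get `NA`.
#'
#' @param panel an imputed [marker_panel()].
#' @param trait a [trait_data()].
#' @param loco list of LOCO kinships from [loco_kinships()].
#' @param training_ids genotypes used for detection (never the validation
#'   set).
#' @return data.frame `marker_id, chromosome, position_cM, effect, p_value`
#'   in map order.
#' @export
gwas_scan <- function(panel, trait, loco, training_ids) {
  stopifnot(inherits(panel, "marker_panel"), inherits(trait, "trait_data"))
  training_ids <- intersect(training_ids, names(trait$values))
  chroms <- unique(panel$map$chromosome)
  if (!all(chroms %in% names(loco))) {
    stop_fatal("LOCO kinship missing for chromosome(s): ",
               paste(setdiff(chroms, names(loco)), collapse = ", "))
  }
  y <- trait$values[training_ids]
  n <- length(y)
  res <- lapply(chroms, function(ch) {
    spec <- mm_spec(trait, training_ids, kernels = list(polygenic = loco[[ch]]))
    vc <- reml_fit(spec)
    H <- record_kernel(spec, 1)
    eg <- eigen(H, symmetric = TRUE)
    dd <- pmax(eg$values, 0) * vc$sigma2[[1]] + vc$sigma2_e
    Ut <- t(eg$vectors)
    yt <- Ut %*% y
    markers <- panel$map$marker_id[panel$map$chromosome == ch]
    eff <- p <- rep(NA_real_, length(markers))
    ones_t <- Ut %*% rep(1, n)
    for (i in seq_along(markers)) {
      x <- panel$dosage[training_ids, markers[i]]
      if (stats::var(x) == 0) next
      Xt <- cbind(ones_t, Ut %*% x)
      XtVX <- crossprod(Xt, Xt / dd)
      XtVy <- crossprod(Xt, yt / dd)
      C <- tryCatch(solve(XtVX), error = function(e) NULL)
      if (is.null(C)) next
      b <- C %*% XtVy
      wald <- b[2]^2 / C[2, 2]
      eff[i] <- b[2]
      p[i] <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
    }
    data.frame(marker_id = markers, chromosome = ch,
               position_cM = panel$map$position_cM[panel$map$chromosome == ch],
               effect = eff, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[match(panel$map$marker_id, out$marker_id), , drop = FALSE]
}

#' Genome-wide significance threshold (effective number of tests)
#'
#' Per-test p-value threshold equivalent to a genome-wide level `alpha`,
#' from the effective number of independent tests: per chromosome the
#' eigenvalues `lambda` of the marker correlation matrix contribute
#' `f(lambda) = I(lambda >= 1) + (lambda - floor(lambda))`, summed over
#' chromosomes to `M_eff`; the threshold is `1 - (1 - alpha)^(1 / M_eff)`.
#' Eigenvalues are rounded at 1e-8 before `floor()` so exact duplicates are
#' not corrupted by floating-point noise.
#'
#' @param panel a [marker_panel()].
#' @param genomewide_alpha genome-wide significance level.
#' @param training_ids genotypes over which marker correlations are
#'   computed; defaults to the whole panel.
#' @return per-test p-value threshold, with `M_eff` attached as an
#'   attribute.
#' @export
li_ji_threshold <- function(panel, genomewide_alpha = 0.01,
                            training_ids = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  if (panel$K < 1) stop_fatal("need at least one marker")
  ids <- training_ids %||% panel$genotype_ids
  d <- panel$dosage[ids, , drop = FALSE]
  meff_chr <- vapply(unique(panel$map$chromosome), function(ch) {
    mk <- panel$map$marker_id[panel$map$chromosome == ch]
    X <- d[, mk, drop = FALSE]
    X <- X[, apply(X, 2, stats::var) > 0, drop = FALSE]
    m <- ncol(X)
    if (m == 0) return(0)
    if (m == 1) return(1)
    if (m <= nrow(X)) {
      ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
    } else {
      Xs <- scale(X)
      ev <- c(svd(Xs, nu = 0, nv = 0)$d^2 / (nrow(X) - 1),
              rep(0, m - nrow(X)))
    }
    ev <- round(pmax(ev, 0), 8)
    sum(ifelse(ev >= 1, 1, 0) + (ev - floor(ev)))
  }, numeric(1))
  meff <- sum(meff_chr)
  if (meff <= 0) stop_fatal("degenerate marker correlation structure")
  thr <- 1 - (1 - genomewide_alpha)^(1 / meff)
  attr(thr, "M_eff") <- meff
  thr
}

#' Collapse significant markers into QTL peaks
#'
#' Keeps markers with `p <= threshold` and greedily collapses them within
#' each chromosome: the smallest-p marker is kept, every other significant
#' marker within `peak_window_cM` of it is dropped, and the rule repeats on
#' the remainder. An empty result is allowed.
#'
#' @param scan data.frame from [gwas_scan()].
#' @param threshold per-test p-value threshold from [li_ji_threshold()].
#' @param peak_window_cM collapse window half-width.
#' @return a [qtl_set()].
#' @export
select_qtl <- function(scan, threshold, peak_window_cM = 20) {
  sig <- scan[!is.na(scan$p_value) & scan$p_value <= threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(qtl_set())
  kept <- list()
  for (ch in unique(sig$chromosome)) {
    s <- sig[sig$chromosome == ch, , drop = FALSE]
    s <- s[order(s$p_value), , drop = FALSE]
    while (nrow(s)) {
      top <- s[1, , drop = FALSE]
      kept[[length(kept) + 1L]] <- top
      s <- s[abs(s$position_cM - top$position_cM) > peak_window_cM, , drop = FALSE]
    }
  }
  k <- do.call(rbind, kept)
  qtl_set(k$marker_id, k$chromosome, k$position_cM, k$p_value)
}

# Rank-one kernel for a single QTL marker: x x' on the 0/1/2 dosage, so the
# QTL effect carries its own variance component.
qtl_kernels <- function(panel, qtl) {
  ks <- lapply(qtl$marker_id, function(mk) {
    x <- panel$dosage[, mk]
    k <- tcrossprod(x)
    dimnames(k) <- list(panel$genotype_ids, panel$genotype_ids)
    k
  })
  names(ks) <- paste0("qtl_", qtl$marker_id)
  ks
}

#' Tune the Gaussian-kernel bandwidth by cross-validation
#'
#' 5-fold cross-validation inside the training set: for each candidate
#' `theta`, the kernel model is refitted on each fold complement and the
#' held-out fold's predictive ability (Pearson correlation) is computed;
#' the `theta` maximizing the mean fold ability wins, ties going to the
#' smallest value. A one-value grid is returned as-is without
#' cross-validation.
#'
#' @param trait a [trait_data()].
#' @param panel an imputed [marker_panel()].
#' @param training_ids training genotypes (at least 15).
#' @param theta_grid candidate bandwidths, conventionally within
#'   \[0.05, 5\].
#' @param n_folds folds.
#' @param seed RNG seed for the fold assignment.
#' @return the selected bandwidth.
#' @export
tune_theta <- function(trait, panel, training_ids,
                       theta_grid = c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 5),
                       n_folds = 5L, seed = 1L) {
  stopifnot(length(theta_grid) >= 1)
  theta_grid <- sort(theta_grid)
  if (length(theta_grid) == 1L) return(theta_grid)
  training_ids <- intersect(training_ids, names(trait$values))
  if (length(training_ids) < 15) {
    stop_fatal("training set too small to cross-validate theta (need >= 15)")
  }
  D <- scaled_sq_dist(panel)
  folds <- with_seed(seed, {
    f <- rep_len(seq_len(n_folds), length(training_ids))
    sample(f)
  })
  score <- vapply(theta_grid, function(th) {
    Kth <- kinship(exp(-D / th), kind = "gaussian", meta = list(theta = th))
    rs <- vapply(seq_len(n_folds), function(fo) {
      hold <- training_ids[folds == fo]
      keep <- setdiff(training_ids, hold)
      spec <- mm_spec(trait, keep, kernels = list(gk = Kth))
      pred <- predict_blup(spec, reml_fit(spec), model = "RKHS")
      obs <- trait$values[hold]
      prd <- pred$predictions[hold]
      if (stats::var(obs) == 0 || stats::var(prd) == 0) return(NA_real_)
      stats::cor(obs, prd)
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  best <- max(score)
  theta_grid[which(score >= best - 1e-12)[1]]   # ties -> smallest theta
}

#' Fit a genomic prediction model
#'
#' The four models share one mixed-model engine and differ in their random
#' terms:
#' * `QTL` — one random effect per detected QTL marker, each with its own
#'   variance (rank-one dosage kernels); requires a non-empty QTL set.
#' * `GBLUP` — a single additive relationship kernel.
#' * `QGBLUP` — the QTL terms plus a polygenic kernel computed with markers
#'   within `mask_window_cM` of each QTL removed; with an empty QTL set it
#'   reduces exactly to GBLUP.
#' * `RKHS` — a Gaussian kernel whose bandwidth is tuned by [tune_theta()]
#'   on the training set.
#'
#' @param model `"QTL"`, `"GBLUP"`, `"QGBLUP"` or `"RKHS"`.
#' @param trait a [trait_data()].
#' @param panel an imputed [marker_panel()].
#' @param training_ids training genotypes.
#' @param qtl a [qtl_set()] (QTL/QGBLUP); forced loci may be merged in via
#'   `forced_qtl`.
#' @param A precomputed additive [kinship()]; computed from the panel when
#'   `NULL`.
#' @param theta_grid bandwidth grid for RKHS.
#' @param mask_window_cM polygenic mask half-width for QGBLUP.
#' @param forced_qtl optional character vector of marker ids always included
#'   as QTL (merged into `qtl` with `NA` p-values).
#' @param seed seed for the RKHS fold assignment.
#' @return a `prediction_result` covering every calibration genotype.
#' @export
fit_prediction_model <- function(model = c("GBLUP", "QTL", "QGBLUP", "RKHS"),
                                 trait, panel, training_ids,
                                 qtl = NULL, A = NULL,
                                 theta_grid = c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 5),
                                 mask_window_cM = 20,
                                 forced_qtl = NULL, seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(panel, "marker_panel"))
  if (!is.null(forced_qtl)) {
    forced_qtl <- setdiff(forced_qtl, qtl$marker_id)
    if (length(forced_qtl)) {
      idx <- match(forced_qtl, panel$map$marker_id)
      if (anyNA(idx)) stop_fatal("forced QTL absent from the panel map")
      add <- qtl_set(forced_qtl, panel$map$chromosome[idx],
                     panel$map$position_cM[idx], rep(NA_real_, length(idx)))
      qtl <- if (is.null(qtl) || nrow(qtl) == 0) add else
        qtl_set(c(qtl$marker_id, add$marker_id),
                c(qtl$chromosome, add$chromosome),
                c(qtl$position_cM, add$position_cM),
                c(qtl$p_value, add$p_value))
    }
  }
  has_qtl <- !is.null(qtl) && nrow(qtl) > 0

  kernels <- switch(
    model,
    QTL = {
      if (!has_qtl) {
        stop_fatal("QTL model requires a non-empty QTL set; ",
                   "fit GBLUP/RKHS when no QTL are detected")
      }
      qtl_kernels(panel, qtl)
    },
    GBLUP = list(additive = A %||% additive_relationship(panel)),
    QGBLUP = {
      poly <- qtl_masked_relationship(panel, qtl, window_cM = mask_window_cM)
      if (has_qtl) c(qtl_kernels(panel, qtl), list(polygenic = poly))
      else list(polygenic = poly)
    },
    RKHS = {
      theta <- tune_theta(trait, panel, training_ids, theta_grid, seed = seed)
      list(gaussian = gaussian_kernel(panel, theta))
    }
  )
  spec <- mm_spec(trait, training_ids, kernels = kernels)
  vc <- reml_fit(spec)
  out <- predict_blup(spec, vc, model = model)
  if (model == "RKHS") out$theta <- kernels$gaussian$meta$theta
  if (model %in% c("QTL", "QGBLUP")) out$qtl <- qtl
  out
}
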