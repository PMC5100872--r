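vc_fixed <- function(sigma2, sigma2_e) {
  structure(list(sigma2 = sigma2, sigma2_e = sigma2_e,
                 lambda = sigma2_e / sigma2[[1]], loglik = NA_real_,
                 converged = TRUE, degenerate = FALSE),
            class = "variance_components")
}

test_that("predict_blup matches the Henderson mixed-model-equation oracle", {
  sim <- simulate_panel(c(15, 15), fst = 0.2, n_markers = 200, seed = 81)
  panel <- sim$panel
  tr <- simulate_trait(panel, n_qtl = 0, h2 = 0.6, seed = 82)
  train <- panel$genotype_ids[1:22]

  # single kernel (ridged so the oracle can invert it)
  Av <- additive_relationship(panel)$values + diag(0.01, 30)
  A <- kinship(Av, kind = "additive_ab")
  spec <- mm_spec(tr$trait, train, kernels = list(additive = A))
  vc <- vc_fixed(c(additive = 0.8), 0.5)
  got <- predict_blup(spec, vc)
  Z <- matrix(0, 22, 30, dimnames = list(train, panel$genotype_ids))
  Z[cbind(seq_len(22), match(train, panel$genotype_ids))] <- 1
  oracle <- mme_oracle(tr$trait$values[train], matrix(1, 22, 1), Z,
                       list(Av), sigma2 = 0.8, sigma2_e = 0.5)
  expect_lt(max(abs(got$predictions - oracle$predictions)), 1e-6)
  expect_equal(got$beta[1], oracle$beta[1], tolerance = 1e-6)

  # two kernels with distinct covariance structures
  G <- gaussian_kernel(panel, theta = 1)
  spec2 <- mm_spec(tr$trait, train, kernels = list(additive = A, gauss = G))
  vc2 <- vc_fixed(c(additive = 0.5, gauss = 0.3), 0.4)
  got2 <- predict_blup(spec2, vc2)
  oracle2 <- mme_oracle(tr$trait$values[train], matrix(1, 22, 1), Z,
                        list(Av, G$values), sigma2 = c(0.5, 0.3),
                        sigma2_e = 0.4)
  expect_lt(max(abs(got2$predictions - oracle2$predictions)), 1e-6)
})

test_that("zero genetic variance predicts the intercept everywhere", {
  panel <- random_panel(12, 30, seed = 83)
  y <- setNames(rnorm(12, 10), panel$genotype_ids)
  A <- additive_relationship(panel)
  spec <- mm_spec(trait_data(y), panel$genotype_ids, kernels = list(a = A))
  got <- predict_blup(spec, vc_fixed(c(a = 0), 1))
  expect_equal(unname(got$predictions), rep(got$beta[1], 12), tolerance = 1e-10)
})

test_that("training predictions shrink toward the mean under an identity kernel", {
  set.seed(84)
  ids <- paste0("g", 1:20)
  I20 <- diag(20); dimnames(I20) <- list(ids, ids)
  y <- setNames(rnorm(20), ids)
  spec <- mm_spec(trait_data(y), ids, kernels = list(a = kinship(I20, "additive_ab")))
  got <- predict_blup(spec, vc_fixed(c(a = 1), 1))
  resid <- y - got$beta[1]
  expect_true(all(abs(got$genetic_values) <= abs(resid) + 1e-10))
})

test_that("single-kernel REML matches brute-force grid maximization of its likelihood", {
  sim <- simulate_panel(c(40, 40), fst = 0.25, n_markers = 800, seed = 85)
  A <- additive_relationship(sim$panel)
  eg <- eigen(A$values, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  set.seed(86)
  y <- setNames(as.numeric(L %*% rnorm(80)) + rnorm(80), A$ids)
  spec <- mm_spec(trait_data(y), A$ids, kernels = list(a = A))
  vc <- reml_fit(spec)
  grid <- 10^seq(-4, 4, length.out = 1000)
  lls <- reml_profile(spec, grid)
  expect_gte(vc$loglik, max(lls) - 1e-6)
  # the optimum also dominates random ratios
  set.seed(87)
  rand <- exp(runif(50, log(1e-4), log(1e4)))
  expect_true(all(vc$loglik >= reml_profile(spec, rand)))
})

test_that("identity-kernel and duplicated-kernel models are flagged degenerate", {
  ids <- paste0("g", 1:30)
  I30 <- diag(30); dimnames(I30) <- list(ids, ids)
  set.seed(88)
  y <- setNames(rnorm(30), ids)
  spec <- mm_spec(trait_data(y), ids, kernels = list(a = kinship(I30, "additive_ab")))
  expect_true(reml_fit(spec)$degenerate)

  A <- additive_relationship(random_panel(20, 50, seed = 89))
  y2 <- setNames(rnorm(20), A$ids)
  spec2 <- mm_spec(trait_data(y2), A$ids, kernels = list(a = A, b = A))
  expect_true(reml_fit(spec2)$degenerate)
})

test_that("multi-kernel REML recovers distinct variance contributions", {
  sim <- simulate_panel(c(60, 60), fst = 0.2, n_markers = 1000, seed = 90)
  panel <- sim$panel
  A <- additive_relationship(panel)
  x <- panel$dosage[, 17]
  qk <- tcrossprod(x)
  dimnames(qk) <- dimnames(A$values)
  eg <- eigen(A$values, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  set.seed(91)
  y <- setNames(2 + 0.8 * x + as.numeric(L %*% rnorm(120)) * 0.7 + rnorm(120, 0, 0.5),
                A$ids)
  spec <- mm_spec(trait_data(y), A$ids,
                  kernels = list(qtl = kinship(qk, "additive_ab"), poly = A))
  vc <- reml_fit(spec)
  expect_true(vc$converged)
  expect_gt(vc$sigma2[["qtl"]], 0)
  expect_gt(vc$sigma2[["poly"]], 0)
  # both terms carry real signal: dropping the QTL term loses likelihood
  spec0 <- mm_spec(trait_data(y), A$ids, kernels = list(poly = A))
  expect_gt(vc$loglik, reml_fit(spec0)$loglik)
})

test_that("GWAS p-values are invariant to consistent relabeling of genotypes", {
  sim <- simulate_panel(c(25, 25), fst = 0.2, n_markers = 120,
                        n_chromosomes = 2, seed = 92)
  panel <- sim$panel
  tr <- simulate_trait(panel, n_qtl = 1, qtl_variance_fraction = 0.5,
                       h2 = 0.7, seed = 93)
  loco <- loco_kinships(panel)
  p1 <- gwas_scan(panel, tr$trait, loco, panel$genotype_ids)

  set.seed(94)
  perm <- sample(panel$genotype_ids)
  panel2 <- subset_panel(panel, genotypes = perm)
  loco2 <- loco_kinships(panel2)
  p2 <- gwas_scan(panel2, tr$trait, loco2, panel2$genotype_ids)
  expect_equal(p1$p_value, p2$p_value[match(p1$marker_id, p2$marker_id)],
               tolerance = 1e-6)
})

test_that("a large simulated QTL is the top association hit", {
  sim <- simulate_panel(c(100, 100), fst = 0.15, n_markers = 500,
                        n_chromosomes = 5, seed = 21)
  panel <- sim$panel
  loco <- cached("gwas_loco", loco_kinships(panel))
  hits <- vapply(1:10, function(i) {
    ts <- simulate_trait(panel, n_qtl = 1, qtl_variance_fraction = 0.5,
                         h2 = 0.6, seed = 2000 + i)
    scan <- gwas_scan(panel, ts$trait, loco, panel$genotype_ids)
    scan$marker_id[which.min(scan$p_value)] == ts$qtl_true$marker_id
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("the effective-test threshold matches closed forms on orthogonal designs", {
  H <- hadamard8()
  d <- (H[, 2:8] + 1)          # 7 exactly orthogonal dosage columns in {0,2}
  rownames(d) <- paste0("g", 1:8)
  panel <- panel_from(d)
  thr <- li_ji_threshold(panel, 0.01)
  expect_equal(attr(thr, "M_eff"), 7, tolerance = 1e-8)
  expect_equal(as.numeric(thr), 1 - 0.99^(1 / 7), tolerance = 1e-10)

  # duplicating every marker must not change the effective count
  d2 <- cbind(d, d)
  colnames(d2) <- paste0("m", 1:14)
  thr2 <- li_ji_threshold(panel_from(d2), 0.01)
  expect_equal(attr(thr2, "M_eff"), 7, tolerance = 1e-8)

  # single marker: the genome-wide level itself
  thr1 <- li_ji_threshold(panel_from(d[, 1, drop = FALSE]), 0.01)
  expect_equal(as.numeric(thr1), 0.01)
})

test_that("the threshold always lies between the Bonferroni bound and alpha", {
  for (seed in c(95, 96)) {
    panel <- random_panel(30, 40, n_chr = 3, seed = seed)
    thr <- li_ji_threshold(panel, 0.01)
    expect_lte(as.numeric(thr), 0.01)
    expect_gte(as.numeric(thr), 1 - 0.99^(1 / panel$K))
  }
})

test_that("peak collapsing keeps one QTL per window", {
  scan <- data.frame(
    marker_id = paste0("m", 1:4),
    chromosome = c("c1", "c1", "c1", "c2"),
    position_cM = c(10, 15, 60, 30),
    effect = 1,
    p_value = c(1e-6, 1e-8, 1e-7, 0.5)
  )
  q <- select_qtl(scan, threshold = 1e-4, peak_window_cM = 20)
  expect_equal(nrow(q), 2L)                   # m2 absorbs m1; m3 is 45 cM away
  expect_setequal(q$marker_id, c("m2", "m3"))
  expect_equal(nrow(select_qtl(scan, threshold = 1e-12)), 0L)
})

test_that("QGBLUP with no QTL reduces exactly to GBLUP", {
  sim <- small_sim()
  tr <- cached("small_trait",
               simulate_trait(sim$panel, n_qtl = 0, h2 = 0.7, seed = 14))
  train <- sim$panel$genotype_ids[1:70]
  A <- additive_relationship(sim$panel)
  g <- fit_prediction_model("GBLUP", tr$trait, sim$panel, train, A = A)
  qg <- fit_prediction_model("QGBLUP", tr$trait, sim$panel, train,
                             qtl = qtl_set(), A = A)
  expect_lt(max(abs(g$predictions - qg$predictions)), 1e-10)
})

test_that("the QTL model requires detected loci; forced loci are merged", {
  sim <- small_sim()
  tr <- cached("small_trait",
               simulate_trait(sim$panel, n_qtl = 0, h2 = 0.7, seed = 14))
  train <- sim$panel$genotype_ids[1:70]
  expect_error(fit_prediction_model("QTL", tr$trait, sim$panel, train,
                                    qtl = qtl_set()),
               "non-empty QTL set")
  forced <- sim$panel$marker_ids[c(3, 50)]
  fit <- fit_prediction_model("QTL", tr$trait, sim$panel, train,
                              qtl = qtl_set(), forced_qtl = forced)
  expect_setequal(fit$qtl$marker_id, forced)
  expect_true(all(is.na(fit$qtl$p_value)))
})

test_that("theta tuning returns a grid value and honors one-point grids", {
  sim <- small_sim()
  tr <- cached("small_trait",
               simulate_trait(sim$panel, n_qtl = 0, h2 = 0.7, seed = 14))
  train <- sim$panel$genotype_ids[1:40]
  expect_equal(tune_theta(tr$trait, sim$panel, train, theta_grid = 2.5), 2.5)
  th <- tune_theta(tr$trait, sim$panel, train, theta_grid = c(0.25, 1, 5),
                   seed = 3)
  expect_true(th %in% c(0.25, 1, 5))
  expect_error(tune_theta(tr$trait, sim$panel, sim$panel$genotype_ids[1:10],
                          theta_grid = c(1, 2)),
               "too small")
})

test_that("RKHS and GBLUP give comparable ability on an additive trait", {
  sim <- study_sim()
  tr <- study_trait()
  A <- cached("study_A", additive_relationship(sim$panel))
  diffs <- vapply(1:5, function(i) {
    sp <- sample_random(sim$panel$genotype_ids, 200, seed = 900 + i)
    g <- fit_prediction_model("GBLUP", tr$trait, sim$panel, sp$training_ids,
                              A = A)
    k <- fit_prediction_model("RKHS", tr$trait, sim$panel, sp$training_ids,
                              theta_grid = c(0.25, 1, 5), seed = i)
    predictive_ability(g, tr$trait, sp$validation_ids) -
      predictive_ability(k, tr$trait, sp$validation_ids)
  }, numeric(1))
  expect_lt(mean(abs(diffs)), 0.08)
})
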