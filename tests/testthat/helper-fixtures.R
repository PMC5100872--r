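# Shared fixtures, built in code. Heavy objects are cached for the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# marker_panel from a bare dosage matrix; markers spread over n_chr groups
panel_from <- function(dosage, n_chr = 1L, positions = NULL) {
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("g%02d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("m%03d", seq_len(ncol(dosage)))
  }
  K <- ncol(dosage)
  chr <- sort(rep_len(seq_len(n_chr), K))
  if (is.null(positions)) positions <- stats::ave(seq_len(K), chr, FUN = seq_along) * 10
  marker_panel(dosage, data.frame(marker_id = colnames(dosage),
                                  chromosome = paste0("c", chr),
                                  position_cM = positions))
}

# random inbred dosage panel; every marker guaranteed polymorphic
random_panel <- function(n, K, n_chr = 2L, seed = 1L) {
  set.seed(seed)
  d <- matrix(2 * rbinom(n * K, 1, runif(K, 0.2, 0.8)[rep(seq_len(K), each = n)]),
              n, K)
  for (k in seq_len(K)) {
    if (length(unique(d[, k])) == 1) {
      flip <- sample.int(n, 1)
      d[flip, k] <- 2 - d[flip, k]
    }
  }
  panel_from(d, n_chr = n_chr)
}

# the structured panel at the study conditions used across the suite
study_sim <- function() {
  cached("study_sim",
         simulate_panel(sizes = c(80, 60, 50, 35, 25), fst = 0.25,
                        n_markers = 2000, n_chromosomes = 5, seed = 11))
}

study_trait <- function() {
  cached("study_trait",
         simulate_trait(study_sim()$panel, n_qtl = 0, h2 = 0.7, seed = 12))
}

# a smaller structured panel for cheaper tests
small_sim <- function() {
  cached("small_sim",
         simulate_panel(sizes = c(40, 30, 30), fst = 0.25, n_markers = 500,
                        n_chromosomes = 3, seed = 2))
}

# IBS kinship where all three genotypes are mutually at distance 0.4
equidistant_ibs <- function() {
  v <- matrix(0.6, 3, 3)
  diag(v) <- 1
  dimnames(v) <- list(paste0("g", 1:3), paste0("g", 1:3))
  kinship(v, kind = "ibs")
}

# Sylvester Hadamard matrix of order 8
hadamard8 <- function() {
  h2 <- matrix(c(1, 1, 1, -1), 2)
  h2 %x% h2 %x% h2
}

# simple Rand index between two label vectors
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Henderson mixed-model-equation oracle: solves for fixed effects and the
# per-term genotype effects directly, given fixed variance components.
mme_oracle <- function(y, X, Z, kernels, sigma2, sigma2_e) {
  m <- length(kernels)
  n_all <- nrow(kernels[[1]])
  Kinvs <- lapply(seq_len(m), function(j) {
    solve(kernels[[j]]) * (sigma2_e / sigma2[j])
  })
  p <- ncol(X)
  dim_tot <- p + m * n_all
  C <- matrix(0, dim_tot, dim_tot)
  rhs <- numeric(dim_tot)
  C[1:p, 1:p] <- crossprod(X)
  rhs[1:p] <- crossprod(X, y)
  for (j in seq_len(m)) {
    rj <- p + (j - 1) * n_all + seq_len(n_all)
    C[1:p, rj] <- crossprod(X, Z)
    C[rj, 1:p] <- crossprod(Z, X)
    rhs[rj] <- crossprod(Z, y)
    for (k in seq_len(m)) {
      ck <- p + (k - 1) * n_all + seq_len(n_all)
      C[rj, ck] <- crossprod(Z)
    }
    C[rj, rj] <- C[rj, rj] + Kinvs[[j]]
  }
  sol <- solve(C, rhs)
  beta <- sol[1:p]
  u <- matrix(sol[-(1:p)], n_all, m)
  list(beta = beta, u = u, predictions = beta[1] + rowSums(u))
}
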