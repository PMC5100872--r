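#' Training/validation split
#'
#' @param method one of `"U"`, `"SU"`, `"CD"`, `"S"`, `"R"`.
#' @param training_ids,validation_ids disjoint genotype id vectors whose
#'   union is the calibration set.
#' @param radius sampling radius (U/SU, units of 1 - IBS), `NA` otherwise.
#' @param seed the seed the split was drawn under.
#' @param cd_trace objective value per accepted exchange (CD only).
#' @return object of class `training_split`.
#' @export
training_split <- function(method, training_ids, validation_ids,
                           radius = NA_real_, seed = NA_integer_,
                           cd_trace = NULL) {
  method <- match.arg(method, c("U", "SU", "CD", "S", "R"))
  if (length(intersect(training_ids, validation_ids))) {
    stop_fatal("training and validation sets overlap")
  }
  structure(
    list(method = method, training_ids = training_ids,
         validation_ids = validation_ids, radius = radius, seed = seed,
         cd_trace = cd_trace),
    class = "training_split"
  )
}

#' @export
print.training_split <- function(x, ...) {
  cat(sprintf("training_split [%s]: %d training / %d validation",
              x$method, length(x$training_ids), length(x$validation_ids)))
  if (!is.na(x$radius)) cat(sprintf(", r = %.4g", x$radius))
  if (!is.null(x$cd_trace)) {
    cat(sprintf(", CD %.4f after %d accepted exchange(s)",
                x$cd_trace[length(x$cd_trace)], length(x$cd_trace) - 1L))
  }
  cat("\n")
  invisible(x)
}

#' Serialize splits to CSV
#'
#' One row per genotype with its role, plus the method, seed and radius.
#' @param split a [training_split()].
#' @param path output CSV.
#' @export
write_split <- function(split, path) {
  dt <- data.table::data.table(
    genotype_id = c(split$training_ids, split$validation_ids),
    role = rep(c("training", "validation"),
               c(length(split$training_ids), length(split$validation_ids))),
    method = split$method, seed = split$seed, radius = split$radius
  )
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

dist_from_ibs <- function(K_ibs) {
  stopifnot(inherits(K_ibs, "kinship"))
  if (K_ibs$kind != "ibs") stop_fatal("expected an IBS kinship")
  1 - K_ibs$values
}

# One maximin elimination pass: repeatedly sample a remaining candidate into
# the training set and discard candidates closer than r (for SU, only those
# in the same stratum). Consumes the current RNG stream.
eliminate_pass <- function(dmat, r, strata = NULL) {
  n <- nrow(dmat)
  pool <- seq_len(n)
  chosen <- integer(0)
  while (length(pool)) {
    pick <- sample_one(pool)
    chosen <- c(chosen, pick)
    near <- dmat[pick, pool] < r
    if (!is.null(strata)) near <- near & strata[pool] == strata[pick]
    pool <- pool[!near & pool != pick]
  }
  chosen
}

#' Find the sampling radius for a target training-set size
#'
#' The uniform-coverage sampler's yield (how many genotypes survive the
#' maximin elimination) shrinks as the radius grows. This searches the
#' empirical grid of candidate radii (midpoints of the sorted unique
#' pairwise 1 - IBS distances, bracketed by half the minimum distance and
#' just above the maximum) by bisection, scoring each candidate by the
#' median yield over `n_probes` elimination passes, and returns the largest
#' radius whose expected yield still reaches the target.
#'
#' @param K_ibs IBS [kinship()] over the calibration set.
#' @param target_size desired training-set size, in `1..n`.
#' @param strata optional [subpop_assignment()]; when given, the yield is
#'   probed under the stratified-uniform discard rule.
#' @param n_probes elimination passes per candidate radius.
#' @return radius (scalar, units of 1 - IBS).
#' @export
find_radius <- function(K_ibs, target_size, strata = NULL, n_probes = 20L) {
  dmat <- dist_from_ibs(K_ibs)
  n <- nrow(dmat)
  if (target_size < 1 || target_size > n) {
    stop_fatal("target_size must be in 1..", n)
  }
  st <- if (is.null(strata)) NULL else strata$groups[rownames(dmat)]
  d <- sort(unique(dmat[upper.tri(dmat)]))
  d <- d[d > 0]
  if (!length(d)) d <- 1e-6
  cand <- c(d[1] / 2,
            if (length(d) > 1) (d[-length(d)] + d[-1]) / 2,
            d[length(d)] * 1.01)

  yield <- function(r) {
    stats::median(vapply(seq_len(n_probes), function(s) {
      length(with_seed(s, eliminate_pass(dmat, r, st)))
    }, numeric(1)))
  }

  lo <- 1L                       # yield(cand[1]) == n >= target always
  hi <- length(cand)
  if (yield(cand[hi]) >= target_size) return(cand[hi])
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (yield(cand[mid]) >= target_size) lo <- mid else hi <- mid
  }
  cand[lo]
}

#' Uniform / stratified-uniform training-set sampling
#'
#' Draws a training set that covers the genetic space uniformly: genotypes
#' are sampled one at a time, and every remaining candidate within distance
#' `r` (1 - IBS) of the new entry is discarded. With `strata`, candidates
#' are discarded only when they are also in the same stratum
#' (stratified-uniform, method `"SU"`), which guarantees every stratum keeps
#' at least one representative. If a pass yields more genotypes than
#' requested, a random subset of exactly `target_size` is kept (for SU the
#' trim preserves one genotype per stratum); if a pass falls short, the
#' radius is shrunk by 5% and the pass rerun, and the radius actually used
#' is recorded on the split.
#'
#' @param K_ibs IBS [kinship()] over the calibration set.
#' @param target_size training-set size.
#' @param seed RNG seed; same seed, same split.
#' @param strata optional [subpop_assignment()] switching to SU.
#' @param r sampling radius; computed by [find_radius()] when `NULL`.
#' @return a [training_split()] with method `"U"` or `"SU"`.
#' @export
sample_uniform <- function(K_ibs, target_size, seed = 1L, strata = NULL,
                           r = NULL) {
  dmat <- dist_from_ibs(K_ibs)
  n <- nrow(dmat)
  if (n == 0) stop_fatal("empty candidate pool")
  if (target_size < 1 || target_size > n) {
    stop_fatal("target_size must be in 1..", n)
  }
  ids <- rownames(dmat)
  st <- if (is.null(strata)) NULL else strata$groups[ids]
  if (is.null(r)) r <- find_radius(K_ibs, target_size, strata = strata)
  stopifnot(r > 0)

  res <- with_seed(seed, {
    r_use <- r
    repeat {
      chosen <- eliminate_pass(dmat, r_use, st)
      if (length(chosen) >= target_size) break
      r_use <- r_use * 0.95
      if (r_use < 1e-12) stop_fatal("radius underflow while matching target size")
    }
    if (length(chosen) > target_size) {
      if (is.null(st)) {
        chosen <- sample_exact(chosen, target_size)
      } else {
        keep <- vapply(split(chosen, st[chosen]), sample_one, numeric(1))
        if (length(keep) > target_size) keep <- sample_exact(keep, target_size)
        extra <- sample_exact(setdiff(chosen, keep),
                              target_size - length(keep))
        chosen <- c(keep, extra)
      }
    }
    list(chosen = sort(chosen), r_use = r_use)
  })
  training_split(if (is.null(strata)) "U" else "SU",
                 ids[res$chosen], ids[-res$chosen],
                 radius = res$r_use, seed = seed)
}

#' Context for the generalized coefficient of determination
#'
#' Precomputes the pieces of the CD criterion that do not depend on the
#' current training set: the (ridge-stabilized) inverse of the additive
#' relationship matrix, and the quadratic forms of the validation contrasts
#' `c_i = e_i - 1/n` (each genotype versus the calibration-set mean).
#' `lambda` is the residual-to-additive variance ratio; use
#' [lambda_from_h2()] to derive it from a heritability.
#'
#' @param A additive-relationship [kinship()] over the calibration set.
#' @param lambda residual/additive variance ratio, `>= 0`.
#' @return object of class `cd_context`.
#' @export
cd_context <- function(A, lambda) {
  stopifnot(inherits(A, "kinship"), lambda >= 0)
  V <- A$values
  n <- nrow(V)
  Ainv <- chol2inv(chol(V + diag(1e-8, n)))
  rmean <- rowMeans(V)
  gmean <- mean(V)
  # c_i' A c_i for every candidate contrast
  cAc <- diag(V) - 2 * rmean + gmean
  structure(
    list(ids = A$ids, n = n, lambda = lambda, Ainv = Ainv, cAc = cAc),
    class = "cd_context"
  )
}

#' Residual-to-additive variance ratio from heritability
#' @param h2 narrow-sense heritability in (0, 1].
#' @return `lambda = (1 - h2) / h2`.
#' @export
lambda_from_h2 <- function(h2) {
  stopifnot(h2 > 0, h2 <= 1)
  (1 - h2) / h2
}

#' Mean generalized coefficient of determination
#'
#' For the given training set, computes the CD of each validation contrast
#' `c_i = e_i - 1/n` (genotype i versus the calibration mean),
#' `CD(c) = c'(A - lambda (Z'MZ + lambda A^{-1})^{-1}) c / (c' A c)`,
#' where `Z` is the training incidence and `M` the projector orthogonal to
#' the intercept over training records, and returns the mean over the
#' validation set. At `lambda = 0` (heritability one) the criterion
#' collapses to 1 for every contrast.
#'
#' @param ctx a [cd_context()].
#' @param training_ids genotype ids currently in the training set.
#' @return mean CD over the validation contrasts.
#' @export
cd_mean <- function(ctx, training_ids) {
  stopifnot(inherits(ctx, "cd_context"))
  tr <- match(training_ids, ctx$ids)
  if (anyNA(tr) || length(tr) == 0) stop_fatal("bad training ids")
  val <- setdiff(seq_len(ctx$n), tr)
  if (!length(val)) stop_fatal("no validation genotypes left")
  if (ctx$lambda == 0) return(1)
  mean(cd_values(ctx, tr, val))
}

# CD per validation contrast, by index. B = Z'MZ + lambda * Ainv where
# Z'MZ = diag(t) - t t' / n_t for an intercept-only fixed design.
cd_values <- function(ctx, tr, val) {
  n <- ctx$n
  t_ind <- rep(0, n)
  t_ind[tr] <- 1
  B <- ctx$lambda * ctx$Ainv
  diag(B) <- diag(B) + t_ind
  B <- B - tcrossprod(t_ind) / length(tr)
  ch <- tryCatch(chol(B), error = function(e) chol(B + diag(1e-8, n)))
  Cv <- matrix(-1 / n, n, length(val))
  Cv[cbind(val, seq_along(val))] <- Cv[cbind(val, seq_along(val))] + 1
  quad <- colSums(Cv * chol2inv_mult(ch, Cv))
  (ctx$cAc[val] - ctx$lambda * quad) / ctx$cAc[val]
}

chol2inv_mult <- function(ch, X) {
  backsolve(ch, forwardsolve(t(ch), X))
}

#' Training-set construction by CD maximization (exchange algorithm)
#'
#' Starts from a random training set of the requested size and proposes
#' single exchanges between a training and a validation genotype, sweeping
#' the swap neighborhood in random order; an exchange is accepted only if
#' the mean validation CD strictly increases, and each acceptance restarts
#' the sweep. The search stops when a complete sweep yields no acceptance
#' (a local optimum of the exchange neighborhood) or after `max_proposals`
#' proposals, whichever comes first. The accepted objective values are
#' recorded in `cd_trace` (non-decreasing by construction).
#'
#' @param A additive-relationship [kinship()] over the calibration set.
#' @param target_size training-set size, `< n`.
#' @param lambda residual/additive variance ratio; see [lambda_from_h2()].
#'   Defaults to the ratio at heritability 0.85.
#' @param seed RNG seed.
#' @param max_proposals exchange proposals before stopping.
#' @return a [training_split()] with method `"CD"`.
#' @export
sample_cd <- function(A, target_size, lambda = lambda_from_h2(0.85),
                      seed = 1L, max_proposals = 800L) {
  stopifnot(inherits(A, "kinship"))
  n <- length(A$ids)
  if (target_size >= n) stop_fatal("target_size must be smaller than the panel")
  ctx <- cd_context(A, lambda)
  res <- with_seed(seed, {
    tr <- sort(sample.int(n, target_size))
    val <- setdiff(seq_len(n), tr)
    cur <- if (lambda == 0) 1 else mean(cd_values(ctx, tr, val))
    trace <- cur
    proposals <- 0L
    n_pairs <- length(tr) * length(val)
    while (lambda > 0 && proposals < max_proposals) {
      order_ <- sample.int(n_pairs)
      improved <- FALSE
      for (idx in order_) {
        if (proposals >= max_proposals) break
        proposals <- proposals + 1L
        i <- ((idx - 1L) %% length(tr)) + 1L
        j <- ((idx - 1L) %/% length(tr)) + 1L
        tr2 <- tr; tr2[i] <- val[j]
        val2 <- val; val2[j] <- tr[i]
        cand <- mean(cd_values(ctx, tr2, val2))
        if (cand > cur) {
          tr <- tr2; val <- val2; cur <- cand
          trace <- c(trace, cur)
          improved <- TRUE
          break                         # acceptance restarts the sweep
        }
      }
      if (!improved) break              # full sweep without acceptance
    }
    list(tr = sort(tr), trace = trace)
  })
  training_split("CD", A$ids[res$tr], A$ids[-res$tr],
                 seed = seed, cd_trace = res$trace)
}

#' Log-proportional stratified sampling
#'
#' Allocates the training set across subpopulations proportionally to the
#' logarithm of subpopulation size,
#' `n_{t,s} = n_t * log(n_s) / sum_s log(n_s)`, rounded by largest remainder
#' so allocations sum exactly to `n_t`. The raw formula can demand more
#' genotypes than a stratum holds (it does for the rice-like case of strata
#' 220/129 at `n_t = 300`); at sampling time allocations are therefore
#' capped at the stratum sizes with the overflow redistributed in remainder
#' order, while [stratified_allocation()] reports the direct arithmetic by
#' default. Singleton strata have `log(1) = 0` and receive nothing under
#' the literal formula. Within each stratum genotypes are drawn uniformly
#' at random.
#'
#' @param assignment a [subpop_assignment()].
#' @param target_size total training-set size.
#' @param seed RNG seed.
#' @return a [training_split()] with method `"S"`.
#' @export
sample_stratified <- function(assignment, target_size, seed = 1L) {
  stopifnot(inherits(assignment, "subpop_assignment"))
  ids <- names(assignment$groups)
  n <- length(ids)
  if (target_size > n) stop_fatal("target_size exceeds the calibration set")
  ns <- as.numeric(assignment$sizes)
  logs <- log(ns)
  if (sum(logs) == 0) {
    stop_fatal("all strata are singletons (log sizes all zero); ",
               "use sample_random() instead")
  }
  alloc <- stratified_allocation(ns, target_size, cap = TRUE)
  names(alloc) <- names(assignment$sizes)

  training <- with_seed(seed, {
    unlist(lapply(names(alloc), function(s) {
      members <- ids[assignment$groups == s]
      sample_exact(members, alloc[[s]])
    }), use.names = FALSE)
  })
  training_split("S", training, setdiff(ids, training), seed = seed)
}

# Largest-remainder rounding of the log-proportional allocation; exported
# workhorse so the arithmetic is testable. With cap = TRUE allocations are
# limited to the stratum sizes and overflow redistributed in remainder order.
#' @rdname sample_stratified
#' @param sizes integer subpopulation sizes.
#' @param cap cap allocations at the stratum sizes (used at sampling time).
#' @export
stratified_allocation <- function(sizes, target_size, cap = FALSE) {
  logs <- log(sizes)
  raw <- target_size * logs / sum(logs)
  alloc <- floor(raw)
  remainder <- raw - alloc
  if (cap) alloc <- pmin(alloc, sizes)
  limit <- if (cap) sizes else rep(Inf, length(sizes))
  left <- target_size - sum(alloc)
  ord <- order(remainder, decreasing = TRUE)
  while (left > 0) {
    progressed <- FALSE
    for (s in ord) {
      if (left == 0) break
      if (alloc[s] < limit[s]) {
        alloc[s] <- alloc[s] + 1
        left <- left - 1
        progressed <- TRUE
      }
    }
    if (!progressed) stop_fatal("target_size exceeds total capacity")
  }
  as.integer(alloc)
}

#' Random training-set sampling
#'
#' Uniform sampling without replacement: every calibration genotype has the
#' same inclusion probability. The baseline every other method is compared
#' against.
#'
#' @param ids calibration genotype ids.
#' @param target_size training-set size.
#' @param seed RNG seed.
#' @return a [training_split()] with method `"R"`. When `target_size == n`
#'   the validation set is empty and a warning is raised.
#' @export
sample_random <- function(ids, target_size, seed = 1L) {
  n <- length(ids)
  if (target_size > n) stop_fatal("target_size exceeds the calibration set")
  training <- with_seed(seed, sample_exact(ids, target_size))
  if (target_size == n) warning("validation set is empty", call. = FALSE)
  training_split("R", training, setdiff(ids, training), seed = seed)
}

#' Distance from each validation genotype to its nearest training entry
#'
#' The accession-to-nearest-entry (A-NE) diagnostic: for every validation
#' genotype, the minimum 1 - IBS distance to any training genotype. Narrow
#' distributions indicate homogeneous coverage of the genetic space.
#'
#' @param K_ibs IBS [kinship()] over the calibration set.
#' @param split a [training_split()] partitioning the kinship's ids.
#' @return named numeric vector ordered like `split$validation_ids`.
#' @export
nearest_entry_distances <- function(K_ibs, split) {
  dmat <- dist_from_ibs(K_ibs)
  if (!length(split$training_ids)) stop_fatal("empty training set")
  if (!setequal(c(split$training_ids, split$validation_ids), rownames(dmat))) {
    stop_fatal("split does not partition the kinship's genotypes")
  }
  sub <- dmat[split$validation_ids, split$training_ids, drop = FALSE]
  stats::setNames(apply(sub, 1, min), split$validation_ids)
}

#' Subpopulation representation relative to random sampling
#'
#' For replicated splits of each method, computes the mean number of
#' training genotypes drawn from each subpopulation and expresses it as a
#' percentage deviation from the mean count realized by random sampling
#' (method `"R"`, which must be present as the baseline).
#'
#' @param splits_by_method named list (method -> list of
#'   [training_split()]s).
#' @param assignment a [subpop_assignment()].
#' @return data.frame with columns `subpopulation`, `size`, and one
#'   percentage-deviation column per non-R method (`NA` where the R baseline
#'   count is zero).
#' @export
representation_table <- function(splits_by_method, assignment) {
  if (!"R" %in% names(splits_by_method)) {
    stop_fatal("random-sampling baseline 'R' is required")
  }
  groups <- names(assignment$sizes)
  mean_counts <- function(splits) {
    rowMeans(vapply(splits, function(sp) {
      tab <- table(factor(assignment$groups[sp$training_ids], levels = groups))
      as.numeric(tab)
    }, numeric(length(groups))))
  }
  base <- mean_counts(splits_by_method[["R"]])
  out <- data.frame(subpopulation = groups,
                    size = as.integer(assignment$sizes),
                    stringsAsFactors = FALSE)
  for (m in setdiff(names(splits_by_method), "R")) {
    mc <- mean_counts(splits_by_method[[m]])
    dev <- ifelse(base > 0, 100 * (mc - base) / base, NA_real_)
    out[[m]] <- dev
  }
  out
}
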