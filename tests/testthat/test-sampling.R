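test_that("find_radius brackets the target size on the three-point configuration", {
  K <- equidistant_ibs()   # all pairwise distances 0.4
  expect_lt(find_radius(K, 2), 0.4)          # r <= 0.4 must be accepted
  expect_lt(find_radius(K, 3), 0.4)          # everyone sampled: r below min distance
  expect_gte(find_radius(K, 1), 0.4)         # one entry: r at least the max distance
  expect_error(find_radius(K, 4), "target_size")
})

test_that("uniform sampling keeps all pairwise training distances at least r", {
  sim <- small_sim()
  K <- ibs_matrix(sim$panel)
  r <- find_radius(K, 40)
  dmat <- 1 - K$values
  for (seed in 1:25) {
    sp <- sample_uniform(K, 40, seed = seed, r = r)
    expect_length(sp$training_ids, 40)
    sub <- dmat[sp$training_ids, sp$training_ids]
    expect_gte(min(sub[upper.tri(sub)]), sp$radius)
  }
})

test_that("duplicate genotypes cannot both enter a uniform training set", {
  d <- rbind(g1 = c(2, 0, 2, 0), g2 = c(2, 0, 2, 0), g3 = c(0, 2, 0, 2),
             g4 = c(0, 2, 2, 0), g5 = c(2, 2, 0, 0))
  K <- ibs_matrix(panel_from(d))
  for (seed in 1:10) {
    sp <- sample_uniform(K, 3, seed = seed, r = 0.1)
    expect_lt(sum(c("g1", "g2") %in% sp$training_ids), 2)
  }
})

test_that("stratified-uniform sampling represents every stratum", {
  # five singleton strata, target 5: each group keeps its only member
  d <- matrix(2 * rbinom(5 * 40, 1, 0.5), 5, 40)
  rownames(d) <- paste0("g", 1:5)
  K <- ibs_matrix(panel_from(d))
  singles <- subpop_assignment(setNames(paste0("s", 1:5), paste0("g", 1:5)))
  sp <- sample_uniform(K, 5, seed = 1, strata = singles, r = 2)
  expect_setequal(sp$training_ids, paste0("g", 1:5))
  expect_identical(sp$method, "SU")

  sim <- small_sim()
  Ks <- ibs_matrix(sim$panel)
  r <- find_radius(Ks, 30, strata = sim$assignment)
  dmat <- 1 - Ks$values
  for (seed in 1:15) {
    sp <- sample_uniform(Ks, 30, seed = seed, strata = sim$assignment, r = r)
    got <- unique(sim$assignment$groups[sp$training_ids])
    expect_setequal(got, names(sim$assignment$sizes))
    # within-stratum minimum distance respects the radius
    for (s in names(sim$assignment$sizes)) {
      mem <- intersect(sp$training_ids,
                       names(sim$assignment$groups)[sim$assignment$groups == s])
      if (length(mem) > 1) {
        sub <- dmat[mem, mem]
        expect_gte(min(sub[upper.tri(sub)]), sp$radius)
      }
    }
  }
})

test_that("cd_mean collapses to one at lambda zero and to zero without kinship links", {
  A <- additive_relationship(random_panel(8, 30, seed = 3))
  ctx0 <- cd_context(A, lambda = 0)
  expect_equal(cd_mean(ctx0, A$ids[1:5]), 1)

  # identity kinship transfers no information to the validation genotype
  I3 <- diag(3)
  dimnames(I3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  ctx <- cd_context(kinship(I3, kind = "additive_ab"), lambda = 1)
  expect_equal(cd_mean(ctx, c("g1", "g2")), 0, tolerance = 1e-6)
})

test_that("cd_mean is non-increasing in lambda", {
  A <- additive_relationship(random_panel(12, 40, seed = 5))
  train <- A$ids[1:8]
  cds <- vapply(c(0, 0.1, 0.5, 1, 2, 10, 100),
                function(l) cd_mean(cd_context(A, l), train), numeric(1))
  expect_true(all(diff(cds) <= 1e-10))
  expect_true(all(cds >= -1e-10 & cds <= 1 + 1e-10))
})

test_that("the CD exchange trace is non-decreasing and beats random splits", {
  sim <- small_sim()
  A <- additive_relationship(sim$panel)
  lam <- lambda_from_h2(0.7)
  ctx <- cd_context(A, lam)
  wins <- 0L
  for (seed in 1:8) {
    sp <- sample_cd(A, 60, lambda = lam, seed = seed)
    expect_true(all(diff(sp$cd_trace) > 0))
    final <- sp$cd_trace[length(sp$cd_trace)]
    rnd <- vapply(1:40, function(i) {
      cd_mean(ctx, sample(A$ids, 60))
    }, numeric(1))
    expect_gt(final, mean(rnd))
    if (final > max(rnd)) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("the exchange reaches the exhaustive optimum when one genotype is validated", {
  panel <- random_panel(15, 60, seed = 71)
  A <- additive_relationship(panel)
  lam <- 1
  ctx <- cd_context(A, lam)
  all_obj <- vapply(seq_along(A$ids), function(v) {
    cd_mean(ctx, A$ids[-v])
  }, numeric(1))
  best <- max(all_obj)
  for (seed in 1:5) {
    sp <- sample_cd(A, 14, lambda = lam, seed = seed)
    expect_equal(sp$cd_trace[length(sp$cd_trace)], best, tolerance = 1e-10)
  }
})

test_that("log-proportional allocation matches the printed two-stratum case", {
  expect_identical(stratified_allocation(c(220, 129), 300), c(158L, 142L))
})

test_that("allocations sum exactly to the target and capped ones respect capacity", {
  set.seed(73)
  for (i in 1:25) {
    S <- sample(2:6, 1)
    sizes <- sample(2:200, S)
    nt <- sample.int(sum(sizes), 1)
    expect_equal(sum(stratified_allocation(sizes, nt)), nt)
    capped <- stratified_allocation(sizes, nt, cap = TRUE)
    expect_equal(sum(capped), nt)
    expect_true(all(capped <= sizes))
    expect_true(all(capped >= 0))
  }
})

test_that("equal strata get equal allocations up to the remainder", {
  alloc <- stratified_allocation(c(50, 50, 50), 100)
  expect_equal(sum(alloc), 100)
  expect_lte(diff(range(alloc)), 1)
})

test_that("singleton strata receive nothing; all-singleton strata are fatal", {
  alloc <- stratified_allocation(c(1, 40, 40), 20)
  expect_equal(alloc[1], 0L)
  asg <- subpop_assignment(setNames(paste0("s", 1:4), paste0("g", 1:4)))
  expect_error(sample_stratified(asg, 2), "singleton")
})

test_that("stratified sampling draws the allocated counts within strata", {
  sim <- small_sim()
  sp <- sample_stratified(sim$assignment, 60, seed = 3)
  alloc <- stratified_allocation(as.numeric(sim$assignment$sizes), 60,
                                 cap = TRUE)
  got <- table(factor(sim$assignment$groups[sp$training_ids],
                      levels = names(sim$assignment$sizes)))
  expect_equal(as.integer(got), alloc)
})

test_that("random sampling gives every genotype equal inclusion probability", {
  ids <- sprintf("g%03d", 1:100)
  inc <- numeric(100)
  for (i in 1:10000) {
    sp <- sample_random(ids, 50, seed = i)
    inc[match(sp$training_ids, ids)] <- inc[match(sp$training_ids, ids)] + 1
  }
  freq <- inc / 10000
  expect_true(all(abs(freq - 0.5) < 0.02))
  expect_identical(sample_random(ids, 50, seed = 1)$training_ids,
                   sample_random(ids, 50, seed = 1)$training_ids)
  expect_warning(sample_random(ids, 100, seed = 1), "empty")
})

test_that("nearest-entry distances are zero for duplicated genotypes and bounded", {
  d <- rbind(g1 = c(2, 0, 2, 0), g2 = c(2, 0, 2, 0), g3 = c(0, 2, 0, 2),
             g4 = c(0, 0, 2, 2))
  K <- ibs_matrix(panel_from(d))
  sp <- training_split("R", c("g1", "g4"), c("g2", "g3"))
  ane <- nearest_entry_distances(K, sp)
  expect_equal(ane[["g2"]], 0)
  dmat <- 1 - K$values
  expect_true(all(ane <= max(dmat)))
  expect_error(nearest_entry_distances(K, training_split("R", character(0),
                                                         rownames(d))),
               "empty")
})

test_that("uniform sampling narrows the nearest-entry distribution versus random", {
  sim <- study_sim()
  K <- cached("study_ibs", ibs_matrix(sim$panel))
  r <- find_radius(K, 150)
  ane_u <- unlist(lapply(1:20, function(i) {
    nearest_entry_distances(K, sample_uniform(K, 150, seed = i, r = r))
  }))
  ane_r <- unlist(lapply(1:20, function(i) {
    nearest_entry_distances(K, sample_random(sim$panel$genotype_ids, 150,
                                             seed = i))
  }))
  expect_lt(IQR(ane_u), IQR(ane_r))
})

test_that("representation deviations vanish for random-vs-random and hit -100 for absence", {
  sim <- small_sim()
  ids <- sim$panel$genotype_ids
  splitsA <- lapply(1:200, function(i) sample_random(ids, 50, seed = i))
  splitsB <- lapply(1:200, function(i) sample_random(ids, 50, seed = 1000 + i))
  tab <- representation_table(list(R = splitsA, R2 = splitsB), sim$assignment)
  expect_true(all(abs(tab$R2) < 5))

  # a method that never samples subpopulation S1
  s1 <- names(sim$assignment$groups)[sim$assignment$groups == "S1"]
  splitsC <- lapply(1:20, function(i) {
    tr <- setdiff(ids, s1)[1:50]
    training_split("S", tr, setdiff(ids, tr))
  })
  tab2 <- representation_table(list(R = splitsA, S = splitsC), sim$assignment)
  expect_equal(tab2$S[tab2$subpopulation == "S1"], -100)
})

test_that("splits serialize with their method metadata", {
  sim <- small_sim()
  K <- ibs_matrix(sim$panel)
  sp <- sample_uniform(K, 30, seed = 4)
  tmp <- tempfile(fileext = ".csv")
  write_split(sp, tmp)
  back <- read.csv(tmp)
  expect_equal(sum(back$role == "training"), 30)
  expect_equal(unique(back$method), "U")
  expect_equal(unique(back$radius), sp$radius)
})
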