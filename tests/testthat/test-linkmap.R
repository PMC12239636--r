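# Pairwise rf estimation, the multipoint error HMM, ordering.

test_that("Haldane and Kosambi conversions round-trip", {
  r <- seq(0, 0.499, by = 0.007)
  expect_equal(cm_to_rf(rf_to_cm(r)), r, tolerance = 1e-12)
  expect_equal(cm_to_rf(rf_to_cm(r, "kosambi"), "kosambi"), r,
               tolerance = 1e-12)
  expect_equal(rf_to_cm(0), 0)
})

test_that("estimate_rf hits the boundary cases", {
  g <- rep(c(0L, 1L, 2L, 1L), 15)
  est <- estimate_rf(g, g)
  expect_equal(est$rf, 0, tolerance = 1e-6)
  expect_gt(est$lod, 5)

  set.seed(51)
  g1 <- sample(0:2, 200, replace = TRUE, prob = c(1, 2, 1) / 4)
  g2 <- sample(0:2, 200, replace = TRUE, prob = c(1, 2, 1) / 4)
  est2 <- estimate_rf(g1, g2)
  # unlinked limit: 3 SE of 0.5 with SE ~ 1/sqrt(2n) gametes
  expect_lt(abs(est2$rf - 0.5), 3 / sqrt(2 * 200))
  expect_lt(est2$lod, 2)

  expect_warning(est3 <- estimate_rf(g1[1:5], g2[1:5]), "fewer than 10")
  expect_true(is.na(est3$rf))
})

test_that("EM recombination fractions match grid-search oracle", {
  set.seed(52)
  for (rep in 1:25) {
    r_true <- runif(1, 0.02, 0.45)
    n <- 50
    # draw from the transmission model: gametes per parent
    rec <- matrix(runif(2 * n) < r_true, n, 2)
    a1 <- rbinom(n, 1, 0.5); a2 <- ifelse(rec[, 1], 1 - a1, a1)
    b1 <- rbinom(n, 1, 0.5); b2 <- ifelse(rec[, 2], 1 - b1, b1)
    g1 <- as.integer(a1 + b1); g2 <- as.integer(a2 + b2)
    miss <- runif(n) < 0.1
    g1[miss] <- NA
    est <- suppressWarnings(estimate_rf(g1, g2))
    oracle <- grid_rf_oracle(g1, g2)
    expect_lt(abs(est$rf - oracle), 1e-3)
  }
})

test_that("X-pair rf uses the single maternal gamete", {
  set.seed(53)
  n <- 120
  sex <- rep(c("M", "F"), length.out = n)
  o1 <- rbinom(n, 1, 0.5)                  # 1 = AZ
  o2 <- ifelse(runif(n) < 0.15, 1 - o1, o1)
  enc <- function(o, sex) ifelse(sex == "M", ifelse(o == 1, 2L, 0L),
                                 ifelse(o == 1, 1L, 0L))
  est <- estimate_rf(enc(o1, sex), enc(o2, sex), sex = sex, x_pair = TRUE)
  expect_equal(est$rf, mean(o1 != o2), tolerance = 1e-12)
})

test_that("error-free HMM map equals chained two-point Haldane distances", {
  g <- small_genome()
  mk <- regular_markers(g)
  sim <- simulate_cross(g, mk, n_f2 = 100, obs = NULL, seed = 61)
  gm <- sim$genotypes
  map <- estimate_map(gm, error_prob = 0)
  for (nm in c("1", "X")) {
    rows <- which(gm$markers$chrom == nm)
    two_pt <- vapply(seq_len(length(rows) - 1), function(k)
      suppressWarnings(estimate_rf(gm$calls[rows[k], gm$ind$generation == "F2"],
                                   gm$calls[rows[k + 1], gm$ind$generation == "F2"],
                                   sex = gm$ind$sex[gm$ind$generation == "F2"],
                                   x_pair = nm == "X"))$rf,
      numeric(1))
    expect_equal(attr(map, "rf")[[nm]], two_pt, tolerance = 1e-4)
  }
})

test_that("zero recombinants give a zero-length group", {
  set.seed(60)
  # every individual identical across 4 markers: no recombinant anywhere
  calls <- matrix(rep(sample(0:2, 20, replace = TRUE), each = 4), 4, 20)
  gm <- make_gm(calls)
  map <- estimate_map(gm, error_prob = 0)
  expect_equal(attr(map, "total_cm"), 0, tolerance = 1e-6)
})

test_that("3-marker rf matches brute-force joint-likelihood grid oracle", {
  set.seed(62)
  n <- 30
  r1t <- 0.12; r2t <- 0.3; e <- 0.001
  draw_gam <- function(r1, r2) {
    a <- rbinom(n, 1, 0.5)
    b <- ifelse(runif(n) < r1, 1 - a, a)
    c <- ifelse(runif(n) < r2, 1 - b, b)
    cbind(a, b, c)
  }
  G <- draw_gam(r1t, r2t) + draw_gam(r1t, r2t)
  obs <- t(G)
  gm <- make_gm(matrix(as.integer(obs), 3, n))
  map <- estimate_map(gm, error_prob = e, tol = 1e-10)
  r_em <- attr(map, "rf")[["1"]]

  # independent brute-force: 4-state phase chain likelihood on a 2-D grid
  t1 <- function(r) matrix(c(1 - r, r, r, 1 - r), 2, 2)
  joint_ll <- function(r1, r2) {
    T1 <- kronecker(t1(r1), t1(r1)); T2 <- kronecker(t1(r2), t1(r2))
    dos <- c(0, 1, 1, 2)
    ll <- 0
    for (i in seq_len(n)) {
      v <- obs[, i]
      e1 <- ifelse(dos == v[1], 1 - e, e / 2)
      a <- rep(0.25, 4) * e1
      a <- (a %*% T1)[1, ] * ifelse(dos == v[2], 1 - e, e / 2)
      a <- (a %*% T2)[1, ] * ifelse(dos == v[3], 1 - e, e / 2)
      ll <- ll + log(sum(a))
    }
    ll
  }
  coarse <- seq(0.005, 0.45, by = 0.005)
  sc <- outer(coarse, coarse, Vectorize(joint_ll))
  best <- arrayInd(which.max(sc), dim(sc))
  fine1 <- seq(max(1e-4, coarse[best[1]] - 0.005),
               coarse[best[1]] + 0.005, by = 2e-4)
  fine2 <- seq(max(1e-4, coarse[best[2]] - 0.005),
               coarse[best[2]] + 0.005, by = 2e-4)
  sf <- outer(fine1, fine2, Vectorize(joint_ll))
  bf <- arrayInd(which.max(sf), dim(sf))
  expect_lt(abs(r_em[1] - fine1[bf[1]]), 1e-3)
  expect_lt(abs(r_em[2] - fine2[bf[2]]), 1e-3)
})

test_that("EM log-likelihood is non-decreasing and declared convergent", {
  g <- small_genome()
  mk <- regular_markers(g)
  sim <- simulate_cross(g, mk, n_f2 = 80, seed = 63)
  gm <- run_qc(sim$genotypes)
  map <- estimate_map(gm)
  for (tr in attr(map, "ll_trace"))
    expect_true(all(diff(tr) > -1e-6))
  expect_true(all(attr(map, "converged")))
})

test_that("noise is absorbed by a matched error model", {
  g <- small_genome()
  mk <- regular_markers(g, spacing_bp = 7.5e5)
  truth_cm <- sum(vapply(g, chrom_map_length, numeric(1)))
  sim <- simulate_cross(g, mk, n_f2 = 500, obs = NULL, seed = 64)
  gm0 <- sim$genotypes
  # noise-free recovery within 10% at n = 500
  map0 <- estimate_map(gm0, error_prob = 0)
  expect_lt(abs(attr(map0, "total_cm") - truth_cm) / truth_cm, 0.10)
  # genotyping noise inflates an error-blind map; a matched error model
  # restores truth within 10%
  set.seed(65)
  noisy <- apply_observation_model(gm0, obs_model(0.01, 0, 0), genome = g)
  # cross-impossible codes carry no signal in the X emission model, so the
  # map can be estimated without dropping flagged markers here
  map_blind <- estimate_map(noisy, error_prob = 0)
  map_match <- estimate_map(noisy, error_prob = 0.01)
  expect_gt(attr(map_blind, "total_cm"), attr(map0, "total_cm"))
  expect_lt(abs(attr(map_match, "total_cm") - truth_cm) / truth_cm, 0.10)
})

test_that("sex-specific maps need both sexes and share the order", {
  g <- small_genome()
  mk <- regular_markers(g)
  sim <- simulate_cross(g, mk, n_f2 = 160, obs = NULL, seed = 66)
  gm <- sim$genotypes
  maps <- sex_specific_maps(gm, error_prob = 0)
  expect_s3_class(maps$male, "genetic_map")
  expect_equal(maps$male$marker, maps$female$marker)
  # no sex-differential process: X lengths agree loosely (shared truth)
  expect_lt(abs(attr(maps$male, "lengths")["X"] -
                  attr(maps$female, "lengths")["X"]), 40)
  few <- gm_subset(gm, ind = c(1:2, which(gm$ind$sex == "F")))
  expect_error(sex_specific_maps(few), "fewer than 10")
})

test_that("ordering recovers swaps and drops cross-linked markers", {
  g <- small_genome()
  mk <- regular_markers(g, spacing_bp = 1.5e6)
  sim <- simulate_cross(g, mk, n_f2 = 400, obs = NULL, seed = 67)
  gm <- sim$genotypes
  rows1 <- which(gm$markers$chrom == "1")
  # swap two adjacent markers physically (positions exchanged)
  i <- rows1[8]; j <- rows1[9]
  swp <- gm
  swp$calls[c(i, j), ] <- swp$calls[c(j, i), ]
  ov <- order_and_validate(gm_subset(swp, markers = rows1))
  ord <- ov$order[["1"]]
  # recovered order un-swaps rows 8 and 9 (up to whole-chromosome flip)
  target <- seq_along(rows1); target[c(8, 9)] <- c(9L, 8L)
  expect_true(identical(ord, target) || identical(ord, rev(target)))

  # a marker from chromosome 2 mislabelled as chromosome 1 is removed
  bad <- gm
  r2 <- which(bad$markers$chrom == "2")[5]
  bad$markers$chrom[r2] <- "1"
  bad$markers$pos[r2] <- max(bad$markers$pos[bad$markers$chrom == "1"]) + 1e5
  o <- order(match(bad$markers$chrom, unique(bad$markers$chrom)),
             bad$markers$pos)
  bad <- gm_subset(bad, markers = o)
  moved <- which(bad$markers$chrom == "1" &
                   bad$markers$pos == max(bad$markers$pos[bad$markers$chrom == "1"]))
  ov2 <- order_and_validate(bad)
  expect_true(moved %in% ov2$removed)

  # an already-optimal order is returned unchanged
  ov3 <- order_and_validate(gm_subset(gm, markers = rows1))
  expect_identical(ov3$order[["1"]], seq_along(rows1))
})
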