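# Filter cascade and cross-design X validation.

test_that("call-quality filter uses strict cutoffs and drops indels", {
  calls <- matrix(1L, 10, 4)
  gq <- matrix(99L, 10, 4)
  dp <- matrix(50L, 10, 4)
  gm <- make_gm(calls, dp = dp, gq = gq)
  # 3 indel ALT alleles
  gm$markers$alt[c(2, 5, 9)] <- c("AT", "ACG", "TTT")
  out <- filter_call_quality(gm)
  expect_equal(nrow(out$markers), 7L)

  gm2 <- make_gm(calls, dp = dp, gq = gq)
  gm2$gq[3, 2] <- 30L  # GQ exactly 30 fails the strict > 30 rule
  gm2$dp[4, 1] <- 20L  # DP exactly 20 fails too
  out2 <- filter_call_quality(gm2)
  expect_true(is.na(out2$calls[3, 2]))
  expect_true(is.na(out2$calls[4, 1]))
  expect_equal(sum(is.na(out2$calls)), 2L)

  # all calls high quality: unchanged
  out3 <- filter_call_quality(make_gm(calls, dp = dp, gq = gq))
  expect_equal(out3$calls, make_gm(calls)$calls)
})

test_that("informative-site selection polarizes against the P0 parents", {
  # 20 sites x (2 P0 + 3 F2); ALT dosage, unpolarized
  set.seed(7)
  calls <- matrix(sample(0:2, 100, replace = TRUE), 20, 5)
  # P0 columns 1 (UT dam) and 2 (AZ sire)
  calls[, 1] <- c(rep(0L, 10), rep(2L, 4), 1L, NA, rep(0L, 4))
  calls[, 2] <- c(rep(2L, 3), rep(0L, 7), rep(0L, 4), 0L, 0L, rep(0L, 4))
  # informative: rows 1-3 (0 vs 2) and 11-14 (2 vs 0); rows 15 het, 16 NA
  gm <- make_gm(calls, generation = c("P0", "P0", "F2", "F2", "F2"),
                sex = c("F", "M", "M", "F", "M"))
  gm$polarized <- FALSE
  gm$markers$origin_az_is_alt <- NULL
  gm$ind$id[1:2] <- c("P0_dam", "P0_sire")
  out <- select_informative_sites(gm)
  expect_equal(nrow(out$markers), 7L)
  expect_true(out$polarized)
  # AZ sire is now always AA (dosage 2), UT dam always BB (0)
  expect_true(all(out$calls[, 1] == 0L))
  expect_true(all(out$calls[, 2] == 2L))
  # chromosome restriction
  gm$markers$chrom[1] <- "scaffold_99"
  out2 <- select_informative_sites(gm, chromosomes = "1")
  expect_equal(nrow(out2$markers), 6L)
  expect_error(select_informative_sites(gm, az_id = "nope"), "P0")
})

test_that("missingness filter is inclusive at the cutoffs, markers first", {
  calls <- matrix(1L, 10, 10)
  gm <- make_gm(calls)
  expect_equal(dim(filter_missingness(gm))[1], 10L)

  gm2 <- make_gm(calls)
  gm2$calls[1, ] <- NA_integer_   # all-NA marker
  gm2$calls[, 2] <- NA_integer_   # all-NA individual
  out <- filter_missingness(gm2)
  expect_equal(dim(out), c(9L, 9L))

  # missing in exactly 68% of individuals: removed (>= is inclusive)
  calls3 <- matrix(1L, 4, 25)
  calls3[2, 1:17] <- NA_integer_  # 17/25 = 0.68
  out3 <- filter_missingness(make_gm(calls3))
  expect_equal(dim(out3)[1], 3L)

  # count mode: fewer than 75 genotypes
  calls4 <- matrix(1L, 3, 100)
  calls4[1, 1:30] <- NA_integer_  # 70 calls < 75
  out4 <- filter_missingness(make_gm(calls4), mode = "count",
                             individual_min_calls = 2)
  expect_equal(dim(out4)[1], 2L)

  gm5 <- make_gm(matrix(NA_integer_, 3, 4))
  expect_error(filter_missingness(gm5), "all data filtered")
})

test_that("thinning keeps one marker per gap, greedy left-to-right", {
  gm <- make_gm(matrix(1L, 3, 4), pos = c(1, 50000, 120000))
  out <- thin_markers(gm, 100000)
  expect_equal(out$markers$pos, c(1, 120000))

  gm1 <- make_gm(matrix(1L, 1, 4), pos = 5e5)
  expect_equal(nrow(thin_markers(gm1)$markers), 1L)

  # greedy oracle on a dense simulated chromosome
  set.seed(31)
  pos <- sort(sample(1:5e6, 400))
  pos <- pos[!duplicated(pos)]
  gm2 <- make_gm(matrix(1L, length(pos), 2), pos = pos)
  out2 <- thin_markers(gm2, 100000)
  keep <- logical(length(pos)); last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= 100000) { keep[i] <- TRUE; last <- pos[i] }
  }
  expect_equal(out2$markers$pos, pos[keep])
})

test_that("impossible X genotypes are flagged and resolved", {
  calls <- matrix(0L, 4, 6)
  sex <- c("M", "M", "F", "F", "M", "F")
  gm <- make_gm(calls, chrom = rep("X", 4), sex = sex)
  gm$calls[1, 1] <- 1L  # male het on X
  gm$calls[1, 3] <- 2L  # female AZ/AZ on X
  gm$calls[2, 2] <- 1L  # male het, single flag
  gm$calls[3, 5] <- 0L  # male BB: fine
  flags <- flag_impossible_x(gm)
  expect_equal(nrow(flags), 3L)
  expect_setequal(flags$reason[flags$marker == 1],
                  c("male_het_X", "female_AZAZ_X"))
  # marker 1 has 2 flags -> dropped; marker 2's single flag -> NA
  out <- resolve_flags(gm, flags)
  expect_equal(nrow(out$markers), 3L)
  expect_true(is.na(out$calls[1, 2]))  # old marker 2 is now row 1
  expect_equal(nrow(flag_impossible_x(out)), 0L)  # idempotent

  # autosomes never flagged
  gma <- make_gm(matrix(1L, 3, 6), sex = sex)
  expect_equal(nrow(flag_impossible_x(gma)), 0L)
  gma$ind$sex[2] <- NA
  expect_error(flag_impossible_x(gma), "unknown sex")

  # no flags: unchanged
  gm0 <- make_gm(matrix(0L, 2, 6), chrom = rep("X", 2), sex = sex)
  expect_identical(resolve_flags(gm0, flag_impossible_x(gm0)), gm0)
})

test_that("flag counts under neo-Y contamination match the binomial oracle", {
  g <- small_genome()
  mk <- regular_markers(g)
  sim <- simulate_cross(g, mk, n_f2 = 150, obs = NULL, seed = 21)
  set.seed(22)
  noisy <- apply_observation_model(sim$genotypes,
                                   obs_model(0, 0, neoy_contamination_rate = 0.1),
                                   genome = g)
  flags <- flag_impossible_x(noisy)
  n_male <- sum(noisy$ind$sex == "M" & noisy$ind$generation == "F2")
  n_reg <- sum(noisy$markers$chrom == "X" & noisy$markers$pos <= 10e6)
  # only male calls whose true code is 0 (UT) become visibly het;
  # AZ-hemizygous calls flip 2 -> 1 too, so all contaminated calls flag
  expected <- n_male * n_reg * 0.1
  expect_lt(abs(nrow(flags) - expected), 3 * sqrt(expected * 0.9) + 1)
})

test_that("segregation distortion drops distorted autosomes, X exempt", {
  mk_counts <- function(n0, n1, n2)
    c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
  calls <- rbind(mk_counts(25, 50, 25), mk_counts(10, 40, 50))
  gm <- make_gm(calls, pos = c(2e5, 4e5))
  out <- segregation_distortion_filter(gm)
  expect_equal(nrow(out$markers), 1L)  # balanced marker kept
  # oracle: chi-square = sum((O-E)^2/E), E = (25, 50, 25)
  chi <- sum((c(50, 40, 10) - c(25, 50, 25))^2 / c(25, 50, 25))
  expect_equal(chi, 36)
  expect_lt(pchisq(chi, 2, lower.tail = FALSE), 0.01)

  # grossly skewed X marker is kept
  gx <- make_gm(rbind(mk_counts(25, 50, 25), mk_counts(90, 0, 10)),
                chrom = c("1", "X"), pos = c(2e5, 4e5))
  outx <- segregation_distortion_filter(gx)
  expect_equal(nrow(outx$markers), 2L)

  # too few calls: skipped with a warning
  g3 <- make_gm(matrix(c(rep(0L, 5), rep(NA_integer_, 95)), 1, 100))
  expect_warning(segregation_distortion_filter(g3), "skipped")
})

test_that("cascade is order-stable and removes nothing from clean data", {
  g <- small_genome()
  mk <- regular_markers(g, spacing_bp = 1.2e6)  # already thinned spacing
  sim <- simulate_cross(g, mk, n_f2 = 120, obs = NULL, seed = 13)
  gm1 <- run_qc(sim$genotypes)
  expect_equal(nrow(gm1$markers), nrow(sim$genotypes$markers))
  expect_equal(nrow(gm1$ind), nrow(sim$genotypes$ind))
  # idempotent: re-running the cascade on its own output changes nothing
  gm2 <- run_qc(gm1)
  expect_equal(gm2$calls, gm1$calls)
  expect_equal(gm2$markers$pos, gm1$markers$pos)
})
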