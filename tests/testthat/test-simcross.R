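# Simulator: meiosis, cross assembly, observation model.

test_that("meiosis respects map length, F1-male X rule, and conservation", {
  set.seed(101)
  flat <- chrom_model("f", 1e6, marey_bp = c(0, 1e6), marey_cm = c(0, 0))
  h1 <- pure_mosaic(1e6, "AZ")
  h2 <- pure_mosaic(1e6, "UT")
  gam <- simulate_meiosis(flat, h1, h2)
  expect_equal(nrow(gam), 1L)  # zero-rate Poisson: one segment

  xchr <- chrom_model("X", 2e6, marey_bp = c(0, 2e6), marey_cm = c(0, 80),
                      is_x = TRUE)
  mosaic <- simulate_meiosis(xchr, h2, h2, is_f1_male_x = TRUE)
  expect_identical(mosaic, h2)  # transmitted intact, no crossover

  chr100 <- chrom_model("c", 5e6, marey_bp = c(0, 5e6), marey_cm = c(0, 100))
  h1b <- pure_mosaic(5e6, "AZ"); h2b <- pure_mosaic(5e6, "UT")
  counts <- vapply(seq_len(10000), function(i)
    mosaic_n_crossovers(simulate_meiosis(chr100, h1b, h2b)), integer(1))
  # Poisson(1) oracle: mean 1, SE = sqrt(1/10000)
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 10000))
  # conservation: segments tile the chromosome
  gams <- replicate(50, simulate_meiosis(chr100, h1b, h2b),
                    simplify = FALSE)
  for (gam in gams) {
    expect_equal(sum(gam$end - gam$start), 5e6)
    if (nrow(gam) > 1)
      expect_true(all(gam$origin[-1] != gam$origin[-nrow(gam)]))
  }
})

test_that("non-monotone Marey curves are rejected at construction", {
  expect_error(chrom_model("b", 1e6, marey_bp = c(0, 5e5, 1e6),
                           marey_cm = c(0, 10, 5)),
               "non-decreasing")
})

test_that("cross design: X constraint, sex ratio, QTL class means", {
  g <- small_genome()
  mk <- regular_markers(g)
  sim <- simulate_cross(g, mk, n_f2 = 200,
                        qtl = qtl_model(chrom = "X", pos_bp = 25e6,
                                        resid_sd = 0),
                        obs = NULL, seed = 42)
  gm <- sim$genotypes
  f2 <- which(gm$ind$generation == "F2")
  x_rows <- gm$markers$chrom == "X"
  sex <- gm$ind$sex[f2]
  calls_x <- gm$calls[x_rows, f2, drop = FALSE]
  # before observation noise: no heterozygous males, no AZ/AZ females
  expect_equal(sum(calls_x[, sex == "M"] == 1L, na.rm = TRUE), 0L)
  expect_equal(sum(calls_x[, sex == "F"] == 2L, na.rm = TRUE), 0L)
  # sex ratio within binomial 99% bounds of 1:1
  n_m <- sum(sex == "M")
  bounds <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(n_m, bounds[1]); expect_lte(n_m, bounds[2])
  # resid_sd 0: male generation time is exactly the hemizygote mean
  ph <- sim$phenotypes
  males <- ph$sex == "M"
  expect_true(all(ph$generation_time[males] %in% c(149, 76)))
  origin <- sim$truth$qtl_origin[males]
  expect_equal(ph$generation_time[males],
               ifelse(origin == "AZ", 149, 76))
  # females: heterozygous mean lies between the UT and AZ means
  expect_true(all(ph$generation_time[!males] %in% c(95, 76)))
})

test_that("viability selection with survival 0 removes all recombinant males", {
  g <- small_genome()
  mk <- regular_markers(g)
  sim <- simulate_cross(g, mk, n_f2 = 120, obs = NULL, seed = 9,
                        viability = viability_model(region = c(0, 30e6),
                                                    male_recombinant_survival = 0))
  males <- which(sim$phenotypes$sex == "M")
  for (i in males)
    expect_equal(mosaic_n_crossovers(sim$truth$maternal[[i]]$X), 0L)
})

test_that("observation model: identity, forced contamination, error counts", {
  g <- small_genome()
  mk <- regular_markers(g)
  sim <- simulate_cross(g, mk, n_f2 = 60, obs = NULL, seed = 3)
  gm0 <- sim$genotypes
  set.seed(11)
  ident <- apply_observation_model(gm0, obs_model(0, 0, 0), genome = g)
  expect_identical(ident$calls, gm0$calls)

  contam <- apply_observation_model(gm0, obs_model(0, 0, 1), genome = g)
  f2 <- which(contam$ind$generation == "F2")
  male <- f2[contam$ind$sex[f2] == "M"]
  reg <- which(contam$markers$chrom == "X" & contam$markers$pos <= 10e6)
  expect_true(all(contam$calls[reg, male] == 1L))

  # binomial oracle for the error rate over an 822 x 181 matrix
  calls <- matrix(0L, 822, 181)
  big <- make_gm(calls, chrom = rep("1", 822), pos = seq_len(822) * 2e5)
  set.seed(5)
  noisy <- apply_observation_model(big, obs_model(0.001, 0, 0), genome = g)
  n_corrupt <- sum(noisy$calls != 0L)
  expected <- 822 * 181 * 0.001
  expect_lt(abs(n_corrupt - expected), 3 * sqrt(expected * 0.999) + 1)
})

test_that("truth crossovers reproduce genotype patterns before noise", {
  g <- small_genome()
  mk <- regular_markers(g)
  sim <- simulate_cross(g, mk, n_f2 = 40, obs = NULL, seed = 8)
  gm <- sim$genotypes
  f2_ids <- sim$phenotypes$id
  for (i in c(1, 17, 40)) {
    j <- match(f2_ids[i], gm$ind$id)
    for (nm in names(g)) {
      rows <- which(gm$markers$chrom == nm)
      pos <- gm$markers$pos[rows]  # no inversions in this genome
      m_az <- mosaic_origin_at(sim$truth$maternal[[i]][[nm]], pos) == "AZ"
      if (nm == "X") {
        expected <- if (gm$ind$sex[j] == "M") ifelse(m_az, 2L, 0L)
                    else as.integer(m_az)
      } else {
        p_az <- mosaic_origin_at(sim$truth$paternal[[i]][[nm]], pos) == "AZ"
        expected <- as.integer(m_az) + as.integer(p_az)
      }
      expect_equal(unname(gm$calls[rows, j]), expected)
    }
  }
})

test_that("simulated depth emulates the three X strata", {
  set.seed(2)
  dep <- simulate_depth(small_genome(), window_bp = 1e6, depth = 30,
                        breaks = c(10e6, 18e6), noise_sd = 0)
  m <- dep[dep$sample == "male" & dep$chrom == "X", ]
  expect_equal(m$depth[m$start < 10e6], rep(30, 10))
  expect_equal(m$depth[m$start >= 18e6], rep(15, 12))
})
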