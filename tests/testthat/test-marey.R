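# Marey maps: inversion runs, rate estimation, gene density.

fake_marey <- function(bp, cm, chrom = "c") {
  structure(data.frame(marker = paste0(chrom, "_", seq_along(bp)),
                       chrom = chrom, pos_bp = bp, pos_cm = cm,
                       stringsAsFactors = FALSE),
            class = c("marey_table", "data.frame"))
}

test_that("inversion runs need more than 10 strictly decreasing markers", {
  bp <- seq(1e6, 30e6, by = 1e6)
  bp[10:21] <- rev(bp[10:21])          # 12-marker reversed block
  t12 <- fake_marey(bp, seq_along(bp))
  calls <- detect_inversions(t12)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_markers, 12L)
  expect_equal(calls$start_bp, 10e6)
  expect_equal(calls$end_bp, 21e6)

  # globally monotone: no calls
  expect_equal(nrow(detect_inversions(fake_marey(bp = seq(1e6, 30e6, 1e6),
                                                 cm = 1:30))), 0L)

  # exactly 10 decreasing markers: not reported
  bp10 <- seq(1e6, 30e6, by = 1e6)
  bp10[10:19] <- rev(bp10[10:19])
  expect_equal(nrow(detect_inversions(fake_marey(bp10, 1:30))), 0L)
  # ...but reported when min_run is lowered
  expect_equal(nrow(detect_inversions(fake_marey(bp10, 1:30), min_run = 10)),
               1L)
})

test_that("reversal restores monotonicity and is a fixed point", {
  bp <- seq(1e6, 30e6, by = 1e6)
  bp[10:21] <- rev(bp[10:21])
  t12 <- fake_marey(bp, seq_along(bp))
  calls <- detect_inversions(t12)
  fixed <- reverse_within_inversions(t12, calls)
  expect_true(all(diff(fixed$pos_bp) > 0))
  expect_equal(nrow(detect_inversions(fixed)), 0L)
  # empty call list: identity
  expect_identical(reverse_within_inversions(t12, detect_inversions(fixed)),
                   t12)
  # overlapping calls rejected
  calls2 <- rbind(calls, calls)
  calls2$start_bp[2] <- calls$start_bp + 1e6
  expect_error(reverse_within_inversions(t12, calls2), "overlapping")
})

test_that("local regression rates recover linear and quadratic truths", {
  mb <- seq(0.5, 40, by = 0.5)
  lin <- fake_marey(mb * 1e6, 1.5 * mb)
  r_lin <- local_recomb_rate(lin)
  expect_equal(r_lin$rate_cm_per_mb, rep(1.5, length(mb)), tolerance = 1e-6)

  # constant plateau: rate ~ 0 there
  cm <- c(seq(0.1, 10, length.out = 20), rep(10, 40),
          seq(10.2, 20, length.out = 20))
  pl <- fake_marey(seq(1, 40, length.out = 80) * 1e6, cm)
  r_pl <- local_recomb_rate(pl, span = 0.3)
  expect_lt(max(abs(r_pl$rate_cm_per_mb[35:45])), 0.15)

  # quadratic truth: derivative 0.02 * Mb within 2% at interior markers
  qd <- fake_marey(mb * 1e6, 0.01 * mb^2)
  r_qd <- local_recomb_rate(qd)
  interior <- mb > 8 & mb < 32
  expect_lt(max(abs(r_qd$rate_cm_per_mb[interior] / (0.02 * mb[interior]) - 1)),
            0.02)

  expect_warning(local_recomb_rate(fake_marey((1:5) * 1e6, 1:5)), "< 10")
})

test_that("gene density uses half-open windows on start coordinates", {
  genes <- data.frame(chrom = "c", start = c(10000, 200000, 499999),
                      type = "gene", biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  d <- gene_density(genes)
  expect_equal(d$n_genes[d$start == 0], 3L)
  # start exactly at 500,000 falls in window 1
  d2 <- gene_density(rbind(genes,
                           data.frame(chrom = "c", start = 500000,
                                      type = "gene",
                                      biotype = "protein_coding")))
  expect_equal(d2$n_genes, c(3L, 1L))

  # GFF3 fixture: 25 genes over 4 windows, hand-enumerated counts
  set.seed(81)
  starts <- c(sample(1:499999, 8), sample(500000:999999, 3),
              sample(1000000:1499999, 9), sample(1500000:1999999, 5))
  fix <- data.frame(chrom = "c", start = starts, type = "gene",
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  path <- write_test_gff(fix)
  d3 <- gene_density(path)
  expect_equal(d3$n_genes, c(8L, 3L, 9L, 5L))
  # conservation: counts sum to genes parsed
  expect_equal(sum(d3$n_genes), 25L)

  # non-protein-coding and non-gene records are not counted
  fix2 <- rbind(fix, data.frame(chrom = "c", start = 100, type = "gene",
                                biotype = "lncRNA"),
                data.frame(chrom = "c", start = 200, type = "exon",
                           biotype = "protein_coding"))
  expect_equal(sum(gene_density(write_test_gff(fix2))$n_genes), 25L)
})

test_that("rate-density regression recovers a noiseless linear relation", {
  set.seed(82)
  dens <- data.frame(chrom = "c", start = (0:79) * 5e5,
                     n_genes = rpois(80, 12), stringsAsFactors = FALSE)
  mb <- seq(0.25, 39.75, by = 0.5)
  rates <- data.frame(marker = paste0("m", seq_along(mb)), chrom = "c",
                      pos_bp = mb * 1e6, stringsAsFactors = FALSE)
  rates$rate_cm_per_mb <- 0.5 +
    0.1 * dens$n_genes[match(floor(rates$pos_bp / 5e5), dens$start / 5e5)]
  fit <- suppressWarnings(rate_density_regression(rates, dens))
  expect_equal(fit$slope, 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_markers_used, 80L)

  # shuffled densities: no relation
  set.seed(83)
  r2s <- replicate(20, {
    sh <- dens; sh$n_genes <- sample(sh$n_genes)
    rate_density_regression(rates, sh)$r_squared
  })
  expect_lt(mean(r2s), 0.05)

  expect_error(rate_density_regression(rates[1:2, ], dens), "fewer than 3")
})

test_that("rates integrate back to the map length on simulated data", {
  g <- small_genome()
  mk <- regular_markers(g, spacing_bp = 6e5)
  sim <- simulate_cross(g, mk, n_f2 = 300, obs = NULL, seed = 84)
  map <- estimate_map(sim$genotypes, error_prob = 0)
  mt <- marey_table(map)
  rates <- local_recomb_rate(mt, span = 0.4)
  for (nm in c("1", "2")) {
    sel <- rates$chrom == nm
    mb <- rates$pos_bp[sel] / 1e6
    rr <- rates$rate_cm_per_mb[sel]
    integral <- sum(diff(mb) * (rr[-1] + rr[-length(rr)]) / 2)
    expect_lt(abs(integral - attr(map, "lengths")[[nm]]) /
                attr(map, "lengths")[[nm]], 0.15)
  }
})

test_that("simulated inversions are detected and fixed in two passes", {
  g <- small_genome(x_inversion = TRUE)
  mk <- regular_markers(g, spacing_bp = 8e5)
  sim <- simulate_cross(g, mk, n_f2 = 350, obs = NULL, seed = 85)
  gm <- sim$genotypes
  ov <- order_and_validate(gm)
  map <- estimate_map(gm, order = ov$order, error_prob = 0)
  mt <- marey_table(map)
  inv <- detect_inversions(mt)
  expect_equal(inv$chrom, "X")
  expect_lt(abs(inv$start_bp - 12e6), 1.6e6)
  expect_lt(abs(inv$end_bp - 24e6), 1.6e6)
  mt2 <- reverse_within_inversions(mt, inv)
  expect_equal(nrow(detect_inversions(mt2)), 0L)  # fixed point in <= 2 passes
  # local rates near the locus are non-negative after reversal
  rr <- local_recomb_rate(mt2, span = 0.5)
  near <- rr$chrom == "X" & rr$pos_bp > 12e6 & rr$pos_bp < 24e6
  expect_gt(min(rr$rate_cm_per_mb[near]), -0.2)
})
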