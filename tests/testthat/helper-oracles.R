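# Independent oracles and small fixtures shared across tests. Each oracle is
# a direct (brute-force or closed-form) implementation kept separate from the
# package's code paths.

# compact 3-chromosome genome (2 autosomes + X) for fast simulations
small_genome <- function(x_inversion = FALSE) {
  list(
    `1` = chrom_model("1", 30e6, marey_bp = c(0, 10e6, 30e6),
                      marey_cm = c(0, 3, 60)),
    `2` = chrom_model("2", 25e6, marey_bp = c(0, 25e6),
                      marey_cm = c(0, 55)),
    X = chrom_model("X", 30e6, marey_bp = c(0, 10e6, 18e6, 30e6),
                    marey_cm = c(0, 31, 39, 70), is_x = TRUE,
                    inversion = if (x_inversion) c(12e6, 24e6),
                    similar_region = c(0, 10e6))
  )
}

regular_markers <- function(genome, spacing_bp = 1e6) {
  do.call(rbind, lapply(names(genome), function(nm)
    data.frame(chrom = nm,
               pos = seq(5e5, genome[[nm]]$length_bp, by = spacing_bp),
               stringsAsFactors = FALSE)))
}

# direct F2 joint-genotype log-likelihood for a marker pair (coupling phase),
# written from the gamete-transmission model, independent of the EM code
pair_loglik_oracle <- function(g1, g2, r) {
  cc <- (1 - r) / 2
  dd <- r / 2
  gam <- list(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  pg <- c(cc, dd, dd, cc)
  P <- matrix(0, 3, 3)
  for (a in 1:4) for (b in 1:4) {
    i <- gam[[a]][1] + gam[[b]][1]
    j <- gam[[a]][2] + gam[[b]][2]
    P[i + 1, j + 1] <- P[i + 1, j + 1] + pg[a] * pg[b]
  }
  ok <- !is.na(g1) & !is.na(g2)
  sum(log(pmax(P[cbind(g1[ok] + 1, g2[ok] + 1)], 1e-300)))
}

# grid-search ML recombination fraction over {0, 1e-4, ..., 0.5}
grid_rf_oracle <- function(g1, g2, step = 1e-4) {
  grid <- seq(0, 0.5, by = step)
  ll <- vapply(grid, function(r) pair_loglik_oracle(g1, g2, r), numeric(1))
  grid[which.max(ll)]
}

# exhaustive minimal crossover count over all gamete assignments; genotype
# codes "0"/"1"/"2" (AZ dosage) or origins "AZ"/"UT"; NA skipped
xo_exhaustive_oracle <- function(seq_codes) {
  v <- seq_codes[!is.na(seq_codes)]
  if (length(v) == 0) return(NA_integer_)
  if (all(v %in% c("AZ", "UT")))
    return(sum(v[-1] != v[-length(v)]))
  g <- as.integer(v)
  L <- length(g)
  if (L == 1) return(0L)
  # gamete pair (a, b) with a + b = g; het positions have 2 phasings
  het <- which(g == 1L)
  base_a <- ifelse(g == 2L, 1L, 0L)
  best <- Inf
  n_h <- length(het)
  for (mask in 0:(2^n_h - 1)) {
    a <- base_a
    if (n_h > 0) {
      bits <- as.integer(intToBits(mask))[seq_len(n_h)]
      a[het] <- bits
    }
    b <- g - a
    xo <- sum(a[-1] != a[-L]) + sum(b[-1] != b[-L])
    if (xo < best) best <- xo
  }
  as.integer(best)
}

# direct-normalization Bayes interval oracle (greedy from peak)
bayes_oracle <- function(pos_cm, lod, prob = 0.95) {
  w <- 10^(lod - max(lod))
  w <- w / sum(w)
  lo <- hi <- which.max(lod)
  mass <- w[lo]
  while (mass < prob && (lo > 1 || hi < length(w))) {
    wl <- if (lo > 1) w[lo - 1] else -Inf
    wr <- if (hi < length(w)) w[hi + 1] else -Inf
    if (wl >= wr) {
      lo <- lo - 1
      mass <- mass + w[lo]
    } else {
      hi <- hi + 1
      mass <- mass + w[hi]
    }
  }
  c(pos_cm[lo], pos_cm[hi])
}

# exact Mann-Whitney U of the first sample, and exact permutation p-value,
# by enumeration over all assignments of the pooled values
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  mu <- length(x) * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(u = u_obs, p = p)
}

# hand-built geno_matrix (polarized), all-F2 unless P0 rows requested
make_gm <- function(calls, chrom = rep("1", nrow(calls)),
                    pos = seq_len(nrow(calls)) * 2e5,
                    sex = rep(c("M", "F"), length.out = ncol(calls)),
                    generation = rep("F2", ncol(calls)),
                    x_chrom = "X", dp = NULL, gq = NULL) {
  n_mk <- nrow(calls)
  markers <- data.frame(chrom = chrom, pos = pos,
                        ref = rep("A", n_mk), alt = rep("C", n_mk),
                        origin_az_is_alt = rep(TRUE, n_mk),
                        stringsAsFactors = FALSE)
  ind <- data.frame(id = sprintf("i%02d", seq_len(ncol(calls))),
                    sex = sex, generation = generation,
                    stringsAsFactors = FALSE)
  geno_matrix(markers, ind, calls, polarized = TRUE, x_chrom = x_chrom,
              dp = dp, gq = gq)
}

# tiny GFF3 text written to a temp file
write_test_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\t%s\t%d\t%d\t.\t+\t.\tID=g%d;gene_biotype=%s",
                     genes$chrom, genes$type, genes$start, genes$start + 999,
                     seq_len(nrow(genes)), genes$biotype))
  writeLines(lines, path)
  path
}
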