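# Pairwise recombination-fraction estimation for an F2 intercross.
#
# Autosomal pairs: both F1 parents are AZ/UT in coupling phase at every locus,
# so each transmits a non-recombinant gamete with probability (1-r) and a
# recombinant one with probability r. The joint genotype table is a function
# of r and the EM algorithm treats the per-gamete recombinant indicators as
# the latent variables; the E-step has a closed form on the 9-cell count
# table, which also lets the EM run vectorized over many pairs at once.
#
# X pairs: every F2 carries a single maternally recombined X whose origin is
# resolved exactly by the cross design (males read directly from hemizygous
# calls; females AB => maternal AZ, BB => maternal UT), so the complete-data
# MLE (the EM fixed point) is direct recombinant counting.

# E-step/M-step/loglik on stacked 9-cell count planes.
# N is a list with elements n22, n21, n20, n12, n11, n10, n02, n01, n00
# (first digit = AZ dosage at marker 1), each a matrix (or scalar) over pairs.
rf_em_f2 <- function(N, tol = 1e-10, maxit = 200) {
  ntot <- N$n22 + N$n21 + N$n20 + N$n12 + N$n11 + N$n10 + N$n02 + N$n01 +
    N$n00
  r <- array(0.25, dim = dim(as.matrix(N$n22)))
  one_rec <- N$n21 + N$n12 + N$n10 + N$n01
  two_rec <- N$n20 + N$n02
  for (it in seq_len(maxit)) {
    cc <- (1 - r) / 2; dd <- r / 2
    # cell (1,1) mixes 0-recombinant (c^2) and 2-recombinant (d^2) pairs
    e11 <- 2 * dd^2 / (cc^2 + dd^2)
    num <- one_rec + 2 * two_rec + N$n11 * e11
    r_new <- pmin(pmax(num / (2 * ntot), 1e-12), 0.5)
    delta <- max(abs(r_new - r), na.rm = TRUE)
    r <- r_new
    if (is.finite(delta) && delta < tol) break
  }
  r
}

rf_loglik_f2 <- function(N, r) {
  cc <- (1 - r) / 2; dd <- r / 2
  lg <- function(x) log(pmax(x, 1e-300))
  N$n22 * lg(cc^2) + N$n00 * lg(cc^2) +
    N$n20 * lg(dd^2) + N$n02 * lg(dd^2) +
    (N$n21 + N$n12 + N$n10 + N$n01) * lg(2 * cc * dd) +
    N$n11 * lg(2 * (cc^2 + dd^2))
}

# 9-cell counts for all marker pairs at once via indicator cross-products
pair_counts <- function(calls) {
  ind <- lapply(0:2, function(v) {
    m <- calls == v
    m[is.na(m)] <- FALSE
    m * 1
  })
  out <- list()
  for (a in 0:2) for (b in 0:2)
    out[[paste0("n", a, b)]] <- tcrossprod(ind[[a + 1]], ind[[b + 1]])
  out
}

#' Pairwise recombination fraction between two markers
#'
#' Maximum-likelihood recombination fraction for one F2 marker pair, with a
#' linkage LOD against r = 0.5. Autosomal pairs are fitted by EM over the
#' phase-known F2 transmission model; X-X pairs use the single maternally
#' recombined gamete, whose origin the cross design resolves exactly.
#'
#' @param g1,g2 Genotype vectors (AZ dosage 0/1/2, `NA` allowed) over the same
#'   individuals.
#' @param sex Sex vector (`"M"`/`"F"`), required for X pairs.
#' @param x_pair Logical; are both markers on the X?
#' @return List with `rf`, `lod`, `n` (jointly non-missing count). `rf` is
#'   `NA` with a warning when `n < 10`.
#' @export
estimate_rf <- function(g1, g2, sex = NULL, x_pair = FALSE) {
  if (x_pair) {
    o1 <- x_gamete_origin(g1, sex)
    o2 <- x_gamete_origin(g2, sex)
    ok <- !is.na(o1) & !is.na(o2)
    n <- sum(ok)
    if (n < 10) {
      warning("fewer than 10 jointly non-missing individuals")
      return(list(rf = NA_real_, lod = NA_real_, n = n))
    }
    n_rec <- sum(o1[ok] != o2[ok])
    rf <- min(n_rec / n, 0.5)
    ll <- function(r) n_rec * log(max(r, 1e-300)) +
      (n - n_rec) * log(max(1 - r, 1e-300))
    lod <- (ll(rf) - ll(0.5)) / log(10)
    return(list(rf = rf, lod = max(lod, 0), n = n))
  }
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n < 10) {
    warning("fewer than 10 jointly non-missing individuals")
    return(list(rf = NA_real_, lod = NA_real_, n = n))
  }
  N <- list()
  for (a in 0:2) for (b in 0:2)
    N[[paste0("n", a, b)]] <- sum(g1[ok] == a & g2[ok] == b)
  rf <- as.numeric(rf_em_f2(N))
  lod <- (rf_loglik_f2(N, rf) - rf_loglik_f2(N, 0.5)) / log(10)
  list(rf = rf, lod = max(as.numeric(lod), 0), n = n)
}

# maternal-gamete origin from X genotype codes: "A" = AZ, "B" = UT
x_gamete_origin <- function(g, sex) {
  if (is.null(sex)) stop("sex required for X markers")
  out <- rep(NA_character_, length(g))
  m <- sex == "M"
  out[m & !is.na(g) & g == 2L] <- "A"
  out[m & !is.na(g) & g == 0L] <- "B"
  out[!m & !is.na(g) & g == 1L] <- "A"
  out[!m & !is.na(g) & g == 0L] <- "B"
  out
}

# Full pairwise rf/lod matrices over all markers of a geno_matrix (F2 only).
# X-X pairs are estimated on resolved maternal-gamete origins; all other
# pairs (including mixed X-autosome pairs, used only for cross-chromosome
# linkage screening) use the autosomal F2 EM.
est_rf_matrix <- function(gm) {
  f2 <- gm_f2(gm)
  calls <- gm$calls[, f2, drop = FALSE]
  sex <- gm$ind$sex[f2]
  n_mark <- nrow(calls)
  N <- pair_counts(calls)
  rf <- rf_em_f2(N)
  lod <- (rf_loglik_f2(N, rf) - rf_loglik_f2(N, 0.5)) / log(10)
  lod[lod < 0] <- 0
  ntot <- Reduce(`+`, N)
  # overwrite X-X pairs with gamete-origin estimates
  x_rows <- which(gm_is_x(gm))
  if (length(x_rows) >= 2) {
    orig <- t(apply(calls[x_rows, , drop = FALSE], 1, x_gamete_origin,
                    sex = sex))
    ia <- (orig == "A"); ia[is.na(ia)] <- FALSE
    ib <- (orig == "B"); ib[is.na(ib)] <- FALSE
    n_rec <- tcrossprod(ia * 1, ib * 1)
    n_rec <- n_rec + t(n_rec)
    n_ok <- tcrossprod((ia | ib) * 1)
    rfx <- pmin(n_rec / pmax(n_ok, 1), 0.5)
    llr <- n_rec * log(pmax(rfx, 1e-300)) +
      (n_ok - n_rec) * log(pmax(1 - rfx, 1e-300))
    ll5 <- n_ok * log(0.5)
    rf[x_rows, x_rows] <- rfx
    lod[x_rows, x_rows] <- pmax((llr - ll5) / log(10), 0)
    ntot[x_rows, x_rows] <- n_ok
  }
  rf[ntot < 10] <- NA
  lod[ntot < 10] <- NA
  diag(rf) <- 0; diag(lod) <- NA
  list(rf = rf, lod = lod, n = ntot)
}
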