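# EM interval mapping. QTL genotype probabilities on a cM grid come from the
# same HMM as map estimation (pseudomarkers are grid points with no data);
# at each position a normal mixture over putative QTL genotypes is fitted by
# EM, with mixing proportions equal to the posterior genotype probabilities,
# and the LOD is log10 of the fitted mixture likelihood over the null
# single-normal likelihood. On the X the genotype classes are the maternal
# gamete's origin {AZ, UT}, the null includes sex as a mean covariate, and
# the QTL model fits origin means within sex.

#' QTL genotype probabilities on a grid
#'
#' Runs the genotyping-error HMM over each chromosome with pseudomarkers
#' inserted every `step_cm`, returning posterior genotype-class probabilities
#' at every grid position (markers always included). Autosomal classes are
#' AZ-dosage {0, 1, 2}; X classes are maternal-gamete origin {AZ, UT}.
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param map A `genetic_map` from [estimate_map()].
#' @param step_cm Grid step in cM.
#' @param error_prob Emission error probability.
#' @return A list per chromosome: `pos_cm`, `pos_bp` (markers exact,
#'   pseudomarkers interpolated), `is_marker`, `n_classes`, and `prob`, an
#'   `n x (n_classes * n_pos)` matrix with classes fastest-varying.
#' @export
calc_genoprob <- function(gm, map, step_cm = 1, error_prob = 0.001) {
  f2 <- gm_f2(gm)
  sex <- gm$ind$sex[f2]
  mnames <- marker_names(gm)
  out <- list()
  for (nm in unique(map$chrom)) {
    sub <- map[map$chrom == nm, , drop = FALSE]
    rows <- match(sub$marker, mnames)
    obs <- gm$calls[rows, f2, drop = FALSE]
    is_x <- nm == attr(map, "x_chrom")
    mcm <- sub$pos_cm
    grid <- sort(unique(c(mcm, seq(0, max(mcm), by = step_cm))))
    mk_at <- match(round(mcm, 9), round(grid, 9))
    K <- length(grid)
    n <- length(f2)
    if (is_x) {
      Em <- x_emission(obs, sex, error_prob)
      S <- 2; init <- c(0.5, 0.5); trans_fun <- x_transition
    } else {
      Em <- auto_emission(obs, error_prob)
      S <- 4; init <- rep(0.25, 4); trans_fun <- auto_transition
    }
    E <- vector("list", K)
    for (k in seq_len(K)) E[[k]] <- matrix(1, n, S)
    for (j in seq_along(mk_at)) E[[mk_at[j]]] <- Em[[j]]
    r <- cm_to_rf(diff(grid), attr(map, "map_function"))
    Tlist <- lapply(pmin(pmax(r, 1e-12), 0.4999), trans_fun)
    fb <- hmm_forward_backward(E, Tlist, init)
    C <- if (is_x) 2L else 3L
    prob <- matrix(0, n, C * K)
    for (k in seq_len(K)) {
      g <- fb$alpha[[k]] * fb$beta[[k]]
      if (is_x) prob[, (C * (k - 1) + 1):(C * k)] <- g
      else {
        prob[, C * (k - 1) + 1] <- g[, 1]
        prob[, C * (k - 1) + 2] <- g[, 2] + g[, 3]
        prob[, C * (k - 1) + 3] <- g[, 4]
      }
    }
    pos_bp <- stats::approx(mcm, sub$pos_bp, xout = grid, rule = 2,
                            ties = "ordered")$y
    out[[nm]] <- list(pos_cm = grid, pos_bp = pos_bp,
                      is_marker = seq_len(K) %in% mk_at, n_classes = C,
                      prob = prob, is_x = is_x)
  }
  attr(out, "ids") <- gm$ind$id[f2]
  attr(out, "sex") <- sex
  out
}

# log-likelihood of a single normal with MLE mean/sd (optionally by group)
null_loglik <- function(y, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(y))
  mu <- stats::ave(y, group)
  s2 <- mean((y - mu)^2)
  sum(stats::dnorm(y, mu, sqrt(s2), log = TRUE))
}

# vectorized-across-positions EM mixture scan for one chromosome.
# W: n x (C*P) weights; y: phenotype; sex used only when is_x.
scan_chrom_em <- function(W, C, y, sex = NULL, is_x = FALSE, tol = 1e-6,
                          maxit = 100) {
  n <- length(y)
  P <- ncol(W) / C
  cls_idx <- lapply(seq_len(C), function(j) seq(j, C * P, by = C))
  expand <- rep(seq_len(P), each = C)
  if (is_x) {
    male <- sex == "M"
    groups <- list(which(male), which(!male))
  } else groups <- list(seq_len(n))
  # init: weighted class means (per sex group on the X), pooled sd
  mu <- matrix(0, length(groups), C * P)
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    sw <- colSums(W[rows, , drop = FALSE])
    swy <- colSums(W[rows, , drop = FALSE] * y[rows])
    mu[gi, ] <- ifelse(sw > 1e-8, swy / pmax(sw, 1e-8), mean(y[rows]))
  }
  sig <- rep(stats::sd(y), P)
  ll <- rep(-Inf, P)
  for (it in seq_len(maxit)) {
    M <- matrix(0, n, C * P)
    for (gi in seq_along(groups)) {
      rows <- groups[[gi]]
      M[rows, ] <- matrix(mu[gi, ], length(rows), C * P, byrow = TRUE)
    }
    sgE <- matrix(sig[expand], n, C * P, byrow = TRUE)
    D <- exp(-0.5 * ((y - M) / sgE)^2) / (sgE * sqrt(2 * pi))
    R <- W * D
    lik <- R[, cls_idx[[1]], drop = FALSE]
    for (j in 2:C) lik <- lik + R[, cls_idx[[j]], drop = FALSE]
    lik <- pmax(lik, 1e-300)
    ll_new <- colSums(log(lik))
    z <- R / lik[, expand, drop = FALSE]
    # M-step
    resid2 <- numeric(P)
    for (gi in seq_along(groups)) {
      rows <- groups[[gi]]
      zz <- z[rows, , drop = FALSE]
      sw <- colSums(zz)
      swy <- colSums(zz * y[rows])
      swy2 <- colSums(zz * y[rows]^2)
      mu[gi, ] <- ifelse(sw > 1e-8, swy / pmax(sw, 1e-8), mu[gi, ])
      r2 <- swy2 - 2 * mu[gi, ] * swy + mu[gi, ]^2 * sw
      resid2 <- resid2 + colSums(matrix(r2, C, P))
    }
    sig <- sqrt(pmax(resid2 / n, 1e-12))
    if (max(abs(ll_new - ll)) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  ll
}

#' Single-QTL genome scan by EM interval mapping
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param map A `genetic_map`.
#' @param phenotype Named numeric vector (names = F2 ids) or a column name of
#'   a phenotype data.frame passed via `pheno`.
#' @param pheno Optional phenotype data.frame (`id`, trait columns).
#' @param step_cm Grid step (markers always included).
#' @param error_prob Emission error probability for genotype probabilities.
#' @param adjust_sex Regress sex out of the phenotype before scanning
#'   autosomes (the X always handles sex in the model itself).
#' @param genoprob Optional precomputed [calc_genoprob()] result.
#' @return A `scan_result`: data.frame (`chrom`, `pos_cm`, `pos_bp`, `lod`,
#'   `is_marker`) with attributes `peak`, `effects` (class means +- SE per
#'   sex at the peak marker), `n`.
#' @export
scan_em <- function(gm, map, phenotype, pheno = NULL, step_cm = 1,
                    error_prob = 0.001, adjust_sex = FALSE,
                    genoprob = NULL) {
  if (is.character(phenotype) && length(phenotype) == 1) {
    stopifnot(!is.null(pheno))
    phenotype <- stats::setNames(pheno[[phenotype]], pheno$id)
  }
  if (is.null(genoprob))
    genoprob <- calc_genoprob(gm, map, step_cm, error_prob)
  ids <- attr(genoprob, "ids")
  sex <- attr(genoprob, "sex")
  y <- phenotype[ids]
  keep <- which(!is.na(y))
  if (length(keep) < 3) stop("too few phenotyped individuals")
  y <- as.numeric(y[keep])
  sex <- sex[keep]
  if (stats::sd(y) < 1e-12) {
    warning("constant phenotype; all lod set to 0")
    zero <- TRUE
  } else zero <- FALSE
  y_auto <- y
  if (adjust_sex && !zero) y_auto <- y - stats::ave(y, sex)
  rows <- list()
  for (nm in names(genoprob)) {
    gp <- genoprob[[nm]]
    P <- length(gp$pos_cm)
    if (zero) {
      lod <- rep(0, P)
    } else if (gp$is_x) {
      W <- gp$prob[keep, , drop = FALSE]
      ll1 <- scan_chrom_em(W, gp$n_classes, y, sex = sex, is_x = TRUE)
      ll0 <- null_loglik(y, sex)
      lod <- pmax((ll1 - ll0) / log(10), 0)
    } else {
      W <- gp$prob[keep, , drop = FALSE]
      ll1 <- scan_chrom_em(W, gp$n_classes, y_auto)
      ll0 <- null_loglik(y_auto)
      lod <- pmax((ll1 - ll0) / log(10), 0)
    }
    rows[[nm]] <- data.frame(chrom = nm, pos_cm = gp$pos_cm,
                             pos_bp = gp$pos_bp, lod = lod,
                             is_marker = gp$is_marker,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pk <- out[which.max(out$lod), , drop = FALSE]
  eff <- peak_effects(gm, map, phenotype, pk$chrom, pk$pos_cm)
  structure(out, peak = pk, effects = eff, n = length(y),
            x_chrom = attr(map, "x_chrom"),
            class = c("scan_result", "data.frame"))
}

# phenotype mean +- SE per genotype class per sex at the marker nearest a peak
peak_effects <- function(gm, map, phenotype, chrom, pos_cm) {
  sub <- map[map$chrom == chrom, ]
  mk <- sub$marker[which.min(abs(sub$pos_cm - pos_cm))]
  row <- match(mk, marker_names(gm))
  f2 <- gm_f2(gm)
  g <- gm$calls[row, f2]
  sex <- gm$ind$sex[f2]
  y <- phenotype[gm$ind$id[f2]]
  if (chrom == gm$x_chrom) {
    cls <- x_gamete_origin(g, sex)
    cls <- ifelse(is.na(cls), NA,
                  ifelse(sex == "M", paste0("hemi_", ifelse(cls == "A", "AZ", "UT")),
                         ifelse(cls == "A", "AZ/UT", "UT/UT")))
  } else {
    cls <- c("UT/UT", "AZ/UT", "AZ/AZ")[g + 1L]
  }
  ok <- !is.na(cls) & !is.na(y)
  agg <- stats::aggregate(y[ok], list(sex = sex[ok], class = cls[ok]),
                          function(v) c(mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v)),
                                        n = length(v)))
  out <- data.frame(sex = agg$sex, class = agg$class, agg$x,
                    marker = mk, stringsAsFactors = FALSE)
  out
}

#' Genome-wide LOD thresholds by permutation, X-specific
#'
#' Permutes the phenotype against the genotypes. With `x_specific = TRUE`
#' the null distributions of the maximum LOD are kept separately for the
#' autosomes and the X, X permutations are stratified within sex, and the
#' significance level is partitioned by map length: `alpha_A = 1 - (1 -
#' alpha)^(L_A/L_T)` and `alpha_X = 1 - (1 - alpha)^(L_X/L_T)`, with
#' thresholds at the corresponding upper quantiles.
#'
#' @param gm,map,phenotype,pheno,step_cm,error_prob,adjust_sex As [scan_em()].
#' @param n_perm Number of permutations (a warning is issued below 100).
#' @param alpha Genome-wide significance level.
#' @param x_specific Partition alpha between autosomes and X.
#' @param seed Integer seed.
#' @param genoprob Optional precomputed [calc_genoprob()] result.
#' @return List: `threshold_auto`, `threshold_x`, `alpha_auto`, `alpha_x`,
#'   `max_auto`, `max_x` (the null maxima).
#' @export
permutation_thresholds <- function(gm, map, phenotype, pheno = NULL,
                                   n_perm = 1000, alpha = 0.05,
                                   x_specific = TRUE, seed = 1,
                                   step_cm = 1, error_prob = 0.001,
                                   adjust_sex = FALSE, genoprob = NULL) {
  if (n_perm < 100) warning("n_perm < 100: unstable quantile estimate")
  if (is.character(phenotype) && length(phenotype) == 1) {
    stopifnot(!is.null(pheno))
    phenotype <- stats::setNames(pheno[[phenotype]], pheno$id)
  }
  if (is.null(genoprob))
    genoprob <- calc_genoprob(gm, map, step_cm, error_prob)
  ids <- attr(genoprob, "ids")
  sex_all <- attr(genoprob, "sex")
  y0 <- phenotype[ids]
  keep <- which(!is.na(y0))
  y0 <- as.numeric(y0[keep])
  sex <- sex_all[keep]
  x_names <- names(genoprob)[vapply(genoprob, `[[`, logical(1), "is_x")]
  auto_names <- setdiff(names(genoprob), x_names)
  Wa <- lapply(genoprob[auto_names], function(gp)
    gp$prob[keep, , drop = FALSE])
  Wx <- lapply(genoprob[x_names], function(gp)
    gp$prob[keep, , drop = FALSE])
  set.seed(seed)
  max_auto <- max_x <- numeric(n_perm)
  m_idx <- which(sex == "M"); f_idx <- which(sex == "F")
  for (p in seq_len(n_perm)) {
    yp <- y0[sample(length(y0))]
    ya <- if (adjust_sex) yp - stats::ave(yp, sex) else yp
    lla0 <- null_loglik(ya)
    best <- 0
    for (nm in auto_names) {
      ll1 <- scan_chrom_em(Wa[[nm]], 3L, ya, tol = 1e-4, maxit = 30)
      best <- max(best, (max(ll1) - lla0) / log(10))
    }
    max_auto[p] <- best
    # X: stratified permutation within sex
    yx <- y0
    yx[m_idx] <- y0[m_idx][sample(length(m_idx))]
    yx[f_idx] <- y0[f_idx][sample(length(f_idx))]
    llx0 <- null_loglik(yx, sex)
    bestx <- 0
    for (nm in x_names) {
      ll1 <- scan_chrom_em(Wx[[nm]], 2L, yx, sex = sex, is_x = TRUE,
                           tol = 1e-4, maxit = 30)
      bestx <- max(bestx, (max(ll1) - llx0) / log(10))
    }
    max_x[p] <- bestx
  }
  lens <- attr(map, "lengths")
  LX <- sum(lens[x_names]); LT <- sum(lens); LA <- LT - LX
  if (x_specific) {
    alpha_a <- 1 - (1 - alpha)^(LA / LT)
    alpha_x <- 1 - (1 - alpha)^(LX / LT)
  } else {
    alpha_a <- alpha_x <- alpha
  }
  list(threshold_auto = as.numeric(stats::quantile(max_auto, 1 - alpha_a)),
       threshold_x = as.numeric(stats::quantile(max_x, 1 - alpha_x)),
       alpha_auto = alpha_a, alpha_x = alpha_x,
       max_auto = max_auto, max_x = max_x)
}

#' Bayes credible interval for QTL location
#'
#' Normalizes `10^lod` over one chromosome's grid to a discrete posterior and
#' expands greedily from the peak, adding whichever neighbouring position
#' carries more mass, until the cumulative mass reaches `prob`.
#'
#' @param scan A `scan_result` (or data.frame with `chrom`, `pos_cm`,
#'   `pos_bp`, `lod`).
#' @param chrom Chromosome to summarize.
#' @param prob Coverage probability (default 0.95).
#' @return List: `chrom`, `cm_lo`, `cm_hi`, `bp_lo`, `bp_hi`, `coverage`.
#' @export
bayes_interval <- function(scan, chrom, prob = 0.95) {
  sub <- scan[scan$chrom == chrom, , drop = FALSE]
  if (all(sub$lod == 0)) {
    warning("all-zero lod; returning whole chromosome")
    return(list(chrom = chrom, cm_lo = min(sub$pos_cm),
                cm_hi = max(sub$pos_cm), bp_lo = min(sub$pos_bp),
                bp_hi = max(sub$pos_bp), coverage = 1))
  }
  w <- 10^(sub$lod - max(sub$lod))
  w <- w / sum(w)
  lo <- hi <- which.max(sub$lod)
  mass <- w[lo]
  while (mass < prob && (lo > 1 || hi < length(w))) {
    wl <- if (lo > 1) w[lo - 1] else -Inf
    wr <- if (hi < length(w)) w[hi + 1] else -Inf
    if (wl >= wr) { lo <- lo - 1; mass <- mass + w[lo] }
    else { hi <- hi + 1; mass <- mass + w[hi] }
  }
  list(chrom = chrom, cm_lo = sub$pos_cm[lo], cm_hi = sub$pos_cm[hi],
       bp_lo = min(sub$pos_bp[c(lo, hi)]), bp_hi = max(sub$pos_bp[c(lo, hi)]),
       coverage = mass)
}

#' @export
print.scan_result <- function(x, ...) {
  pk <- attr(x, "peak")
  cat(sprintf("<scan_result: %d positions; peak lod %.2f on %s at %.1f cM>\n",
              nrow(x), pk$lod, pk$chrom, pk$pos_cm))
  invisible(x)
}
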