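# Multipoint map estimation: EM on a hidden Markov model whose hidden states
# are true F2 genotypes. Autosomes use a 4-state phase-known chain (the
# maternal and paternal gamete's AZ dosage), which collapses to the usual
# 3-state genotype model in the likelihood but gives the M-step a closed form
# (expected recombinant gamete transitions). The X uses a 2-state chain over
# the maternal gamete's origin, with sex-specific emissions. Emissions allow
# mis-genotyping with probability error_prob (a wrong call is any of the
# other codes, equiprobable).

AUTO_DOSAGE <- c(0L, 1L, 1L, 2L)  # states (0,0),(0,1),(1,0),(1,1)
AUTO_HAMMING <- outer(c(0, 0, 1, 1), c(0, 0, 1, 1), function(a, b) abs(a - b)) +
  outer(c(0, 1, 0, 1), c(0, 1, 0, 1), function(a, b) abs(a - b))

auto_transition <- function(r) {
  t1 <- matrix(c(1 - r, r, r, 1 - r), 2, 2)
  kronecker(t1, t1)
}

x_transition <- function(r) matrix(c(1 - r, r, r, 1 - r), 2, 2)

# emission matrices, one n x S matrix per marker
auto_emission <- function(obs, error_prob) {
  lapply(seq_len(nrow(obs)), function(k) {
    v <- obs[k, ]
    E <- matrix(1, length(v), 4)
    for (s in 1:4) {
      p <- ifelse(v == AUTO_DOSAGE[s], 1 - error_prob, error_prob / 2)
      E[, s] <- ifelse(is.na(v), 1, p)
    }
    pmax(E, 1e-12)
  })
}

# X states: 1 = maternal AZ, 2 = maternal UT
x_emission <- function(obs, sex, error_prob) {
  male <- sex == "M"
  lapply(seq_len(nrow(obs)), function(k) {
    v <- obs[k, ]
    # implied origin of each observed code; impossible codes carry no signal
    orig <- rep(NA_integer_, length(v))
    orig[male & !is.na(v) & v == 2L] <- 1L
    orig[male & !is.na(v) & v == 0L] <- 2L
    orig[!male & !is.na(v) & v == 1L] <- 1L
    orig[!male & !is.na(v) & v == 0L] <- 2L
    E <- matrix(1, length(v), 2)
    ok <- !is.na(orig)
    E[ok, 1] <- ifelse(orig[ok] == 1L, 1 - error_prob, error_prob)
    E[ok, 2] <- ifelse(orig[ok] == 2L, 1 - error_prob, error_prob)
    pmax(E, 1e-12)
  })
}

# scaled forward-backward over all individuals at once
hmm_forward_backward <- function(E, Tlist, init) {
  K <- length(E); n <- nrow(E[[1]]); S <- ncol(E[[1]])
  alpha <- vector("list", K)
  cvec <- matrix(0, n, K)
  a <- sweep(E[[1]], 2, init, "*")
  c1 <- rowSums(a)
  alpha[[1]] <- a / c1
  cvec[, 1] <- c1
  if (K > 1) for (k in 2:K) {
    a <- (alpha[[k - 1]] %*% Tlist[[k - 1]]) * E[[k]]
    ck <- rowSums(a)
    alpha[[k]] <- a / ck
    cvec[, k] <- ck
  }
  beta <- vector("list", K)
  beta[[K]] <- matrix(1, n, S)
  if (K > 1) for (k in (K - 1):1) {
    beta[[k]] <- ((beta[[k + 1]] * E[[k + 1]]) %*% t(Tlist[[k]])) /
      cvec[, k + 1]
  }
  list(alpha = alpha, beta = beta, cvec = cvec, ll = sum(log(cvec)))
}

# EM for one chromosome; obs is a K x n matrix of codes, r a K-1 init vector
est_chrom_map_em <- function(obs, is_x, sex, error_prob, r_init,
                             tol = 1e-6, maxit = 1000) {
  K <- nrow(obs)
  n <- ncol(obs)
  if (K == 1)
    return(list(r = numeric(0), ll = 0, ll_trace = numeric(0),
                converged = TRUE, gamma = NULL))
  E <- if (is_x) x_emission(obs, sex, error_prob)
       else auto_emission(obs, error_prob)
  init <- if (is_x) c(0.5, 0.5) else rep(0.25, 4)
  trans_fun <- if (is_x) x_transition else auto_transition
  r <- pmin(pmax(r_init, 1e-6), 0.499)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  fb <- NULL
  for (it in seq_len(maxit)) {
    Tlist <- lapply(r, trans_fun)
    fb <- hmm_forward_backward(E, Tlist, init)
    ll_trace <- c(ll_trace, fb$ll)
    if (is.finite(ll_old) && abs(fb$ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- fb$ll
    for (k in seq_len(K - 1)) {
      B <- (E[[k + 1]] * fb$beta[[k + 1]]) / fb$cvec[, k + 1]
      C <- crossprod(fb$alpha[[k]], B) * Tlist[[k]]
      if (is_x) {
        r[k] <- (C[1, 2] + C[2, 1]) / sum(C)
      } else {
        r[k] <- sum(C * AUTO_HAMMING) / (2 * sum(C))
      }
      r[k] <- min(max(r[k], 1e-9), 0.499)
    }
  }
  gamma <- lapply(seq_len(K), function(k) fb$alpha[[k]] * fb$beta[[k]])
  list(r = r, ll = fb$ll, ll_trace = ll_trace, converged = converged,
       gamma = gamma)
}

# two-point initial rf for adjacent markers
adjacent_rf_init <- function(obs, is_x, sex) {
  K <- nrow(obs)
  if (K < 2) return(numeric(0))
  vapply(seq_len(K - 1), function(k) {
    est <- suppressWarnings(
      estimate_rf(obs[k, ], obs[k + 1, ], sex = sex, x_pair = is_x))
    if (is.na(est$rf)) 0.1 else min(max(est$rf, 1e-4), 0.45)
  }, numeric(1))
}

#' Estimate a multipoint genetic map
#'
#' Fits, per chromosome, the genotyping-error HMM by EM: the E-step runs
#' forward-backward over all individuals, the M-step updates each adjacent
#' recombination fraction from the expected transition counts, and iteration
#' stops when the log-likelihood changes by less than `tol` (non-convergence
#' returns the best estimate with `converged = FALSE`). Recombination
#' fractions are converted to cM by the map function. If `error_lod_cutoff`
#' is set, calls whose posterior error odds exceed `10^error_lod_cutoff` are
#' set missing and the map re-estimated once.
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param order Optional per-chromosome list of marker row indices (map
#'   order), e.g. from [order_and_validate()]; default physical order.
#' @param error_prob Genotyping-error probability of the emission model.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param tol,maxit EM convergence controls.
#' @param error_lod_cutoff Optional log10 posterior-error-odds cutoff for
#'   flagging calls (e.g. 4); `NULL` disables flagging.
#' @param individuals Optional subset of F2 ids to use.
#' @return A `genetic_map`: data.frame (`chrom`, `marker`, `pos_bp`,
#'   `pos_cm`) with attributes `lengths`, `total_cm`, `rf`, `loglik`,
#'   `ll_trace`, `converged`, `n_flagged`.
#' @export
estimate_map <- function(gm, order = NULL, error_prob = 0.001,
                         map_function = c("haldane", "kosambi"),
                         tol = 1e-6, maxit = 1000, error_lod_cutoff = NULL,
                         individuals = NULL) {
  map_function <- match.arg(map_function)
  f2 <- gm_f2(gm)
  if (!is.null(individuals)) f2 <- f2[gm$ind$id[f2] %in% individuals]
  sex <- gm$ind$sex[f2]
  chroms <- unique(gm$markers$chrom)
  if (is.null(order)) {
    order <- lapply(chroms, function(nm) which(gm$markers$chrom == nm))
    names(order) <- chroms
  } else {
    chroms <- intersect(chroms, names(order))
  }

  fit_all <- function(calls) {
    res <- list()
    for (nm in chroms) {
      idx <- order[[nm]]
      obs <- calls[idx, , drop = FALSE]
      is_x <- nm == gm$x_chrom
      r0 <- adjacent_rf_init(obs, is_x, sex)
      res[[nm]] <- est_chrom_map_em(obs, is_x, sex, error_prob, r0,
                                    tol = tol, maxit = maxit)
    }
    res
  }
  calls <- gm$calls[, f2, drop = FALSE]
  res <- fit_all(calls)

  n_flagged <- 0L
  if (!is.null(error_lod_cutoff)) {
    for (nm in chroms) {
      idx <- order[[nm]]
      is_x <- nm == gm$x_chrom
      gam <- res[[nm]]$gamma
      if (is.null(gam)) next
      for (kk in seq_along(idx)) {
        v <- calls[idx[kk], ]
        p_match <- rep(NA_real_, length(v))
        if (is_x) {
          orig <- x_gamete_origin(v, sex)
          ok <- !is.na(orig)
          p_match[ok] <- gam[[kk]][cbind(which(ok),
                                         ifelse(orig[ok] == "A", 1L, 2L))]
        } else {
          ok <- !is.na(v)
          for (s in 0:2) {
            sel <- ok & v == s
            if (any(sel))
              p_match[sel] <- rowSums(
                gam[[kk]][sel, AUTO_DOSAGE == s, drop = FALSE])
          }
        }
        p_match <- pmin(pmax(p_match, 0), 1)
        elod <- log10((1 - p_match) / pmax(p_match, 1e-300))
        bad <- which(!is.na(elod) & elod > error_lod_cutoff)
        if (length(bad)) {
          calls[idx[kk], bad] <- NA_integer_
          n_flagged <- n_flagged + length(bad)
        }
      }
    }
    if (n_flagged > 0) res <- fit_all(calls)
  }

  rows <- list()
  lengths <- numeric(0)
  rf <- loglik <- ll_trace <- list()
  converged <- logical(0)
  for (nm in chroms) {
    idx <- order[[nm]]
    cm <- c(0, cumsum(rf_to_cm(res[[nm]]$r, map_function)))
    rows[[nm]] <- data.frame(
      chrom = nm,
      marker = marker_names(gm)[idx],
      pos_bp = gm$markers$pos[idx],
      pos_cm = cm, stringsAsFactors = FALSE)
    lengths[nm] <- cm[length(cm)]
    rf[[nm]] <- res[[nm]]$r
    loglik[[nm]] <- res[[nm]]$ll
    ll_trace[[nm]] <- res[[nm]]$ll_trace
    converged[nm] <- res[[nm]]$converged
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, lengths = lengths, total_cm = sum(lengths), rf = rf,
            loglik = loglik, ll_trace = ll_trace, converged = converged,
            map_function = map_function, error_prob = error_prob,
            n_flagged = n_flagged, x_chrom = gm$x_chrom,
            class = c("genetic_map", "data.frame"))
}

marker_names <- function(gm) paste0(gm$markers$chrom, "_", gm$markers$pos)

#' @export
print.genetic_map <- function(x, ...) {
  len <- attr(x, "lengths")
  cat(sprintf("<genetic_map: %d markers, %d groups, total %.1f cM>\n",
              nrow(x), length(len), attr(x, "total_cm")))
  print(round(len, 1))
  invisible(x)
}

#' Sex-specific genetic maps
#'
#' Re-runs [estimate_map()] separately on the male-only and female-only F2
#' submatrices under a shared marker order. No normalization is applied: both
#' sexes inherit exactly one maternally recombined X, so the X maps are
#' directly comparable.
#'
#' @param gm A polarized, QC'd `geno_matrix`.
#' @param order Optional per-chromosome order (see [estimate_map()]).
#' @param ... Passed to [estimate_map()].
#' @return List with components `male` and `female`, each a `genetic_map`.
#' @export
sex_specific_maps <- function(gm, order = NULL, ...) {
  f2 <- gm_f2(gm)
  for (s in c("M", "F")) {
    if (sum(gm$ind$sex[f2] == s) < 10)
      stop("fewer than 10 F2 individuals of sex ", s)
  }
  ids_m <- gm$ind$id[f2][gm$ind$sex[f2] == "M"]
  ids_f <- gm$ind$id[f2][gm$ind$sex[f2] == "F"]
  list(male = estimate_map(gm, order = order, individuals = ids_m, ...),
       female = estimate_map(gm, order = order, individuals = ids_f, ...))
}
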