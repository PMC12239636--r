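# Marey maps: per-marker (physical bp, genetic cM) pairs per chromosome.
# Local slope is the recombination rate; runs of markers whose physical
# position decreases along the map reveal putative inversions relative to
# the reference assembly (or reference mis-scaffolds - the calls stay
# "putative").

#' Build a Marey table from a genetic map
#'
#' Markers at identical cM (no recombinant separates them) have no
#' linkage-identifiable internal order; with `orient_ties = TRUE` (default)
#' each tie block is sorted so its physical positions continue the trend of
#' the flanking markers — the most parsimonious choice, and the one that lets
#' reversed (inverted) runs surface instead of being broken by arbitrary
#' within-tie order.
#'
#' @param map A `genetic_map` (or data.frame with `chrom`, `marker`,
#'   `pos_bp`, `pos_cm`).
#' @param orient_ties Orient cM-tie blocks along the local physical trend.
#' @return A `marey_table`: rows sorted by cM within chromosome.
#' @export
marey_table <- function(map, orient_ties = TRUE) {
  df <- as.data.frame(map)[, c("marker", "chrom", "pos_bp", "pos_cm")]
  df <- df[order(match(df$chrom, unique(df$chrom)), df$pos_cm), ]
  rownames(df) <- NULL
  if (orient_ties) {
    for (nm in unique(df$chrom)) {
      sel <- which(df$chrom == nm)
      cm <- df$pos_cm[sel]
      # ties up to numerical tolerance (rf floored at ~1e-9 in estimation)
      blocks <- split(seq_along(sel), cumsum(c(TRUE, diff(cm) > 1e-3)))
      # orientation decided from the pre-orientation means of the flanking
      # blocks only (no cascade); edge blocks stay ascending, so a long
      # suppressed stretch at a chromosome end cannot fabricate a run
      means <- vapply(blocks, function(b) mean(df$pos_bp[sel[b]]),
                      numeric(1))
      for (k in seq_along(blocks)) {
        b <- blocks[[k]]
        if (length(b) < 2) next
        decreasing <- k > 1 && k < length(blocks) &&
          means[k + 1] < means[k - 1]
        o <- order(df$pos_bp[sel[b]], decreasing = decreasing)
        df[sel[b], ] <- df[sel[b][o], ]
      }
    }
    rownames(df) <- NULL
  }
  structure(df, class = c("marey_table", "data.frame"))
}

#' Detect putative inversions
#'
#' Finds maximal runs of consecutive markers (in map order) whose physical
#' position strictly decreases; runs of at least `min_run` markers (default
#' 11, i.e. more than 10) are reported with endpoints at the minimum and
#' maximum physical position among the run's markers.
#'
#' @param t A [marey_table()].
#' @param min_run Minimum run length to report.
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `n_markers`, `markers`
#'   (comma-separated ids).
#' @export
detect_inversions <- function(t, min_run = 11) {
  calls <- list()
  for (nm in unique(t$chrom)) {
    sub <- t[t$chrom == nm, , drop = FALSE]
    if (nrow(sub) < 2) next
    dec <- diff(sub$pos_bp) < 0
    # run of d consecutive decreasing steps = d + 1 markers
    r <- rle(dec)
    pos <- cumsum(c(1, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      n_mk <- r$lengths[j] + 1L
      if (n_mk < min_run) next
      i0 <- pos[j]
      idx <- i0:(i0 + n_mk - 1L)
      calls[[length(calls) + 1]] <- data.frame(
        chrom = nm, start_bp = min(sub$pos_bp[idx]),
        end_bp = max(sub$pos_bp[idx]), n_markers = n_mk,
        markers = paste(sub$marker[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_markers = integer(),
                      markers = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Reverse marker order within putative inversions
#'
#' Within each call, the run's physical positions are re-assigned in reversed
#' order (the cM order is untouched), restoring a locally monotone Marey
#' relation so local recombination rates are not forced negative.
#'
#' @param t A [marey_table()].
#' @param calls Output of [detect_inversions()].
#' @return Corrected `marey_table`.
#' @export
reverse_within_inversions <- function(t, calls) {
  if (nrow(calls) == 0) return(t)
  for (nm in unique(calls$chrom)) {
    cc <- calls[calls$chrom == nm, , drop = FALSE]
    if (nrow(cc) > 1) {
      o <- order(cc$start_bp)
      cc <- cc[o, ]
      if (any(cc$end_bp[-nrow(cc)] > cc$start_bp[-1]))
        stop("overlapping inversion calls on chromosome ", nm)
    }
  }
  for (k in seq_len(nrow(calls))) {
    ids <- strsplit(calls$markers[k], ",", fixed = TRUE)[[1]]
    idx <- match(ids, t$marker)
    t$pos_bp[idx] <- rev(t$pos_bp[idx])
  }
  t
}

# tricube-weighted local polynomial fit; returns the derivative at x0
local_slope <- function(x, y, x0, span, degree = 2) {
  n <- length(x)
  k <- max(degree + 2, ceiling(span * n))
  d <- abs(x - x0)
  h <- sort(d)[min(k, n)]
  w <- (1 - pmin(d / max(h, 1e-12), 1)^3)^3
  use <- w > 0
  if (sum(use) < degree + 1) {
    use <- rank(d, ties.method = "first") <= degree + 1
    w[use] <- 1
  }
  xc <- x[use] - x0
  X <- stats::poly(xc, degree = degree, raw = TRUE, simple = TRUE)
  X <- cbind(1, X)
  fit <- stats::lm.wfit(X, y[use], w[use])
  unname(fit$coefficients[2])
}

#' Local recombination rate at each marker
#'
#' Per chromosome, a locally weighted polynomial regression of genetic
#' position (cM) on physical position (Mb) — tricube weights, window holding
#' a `span` fraction of the chromosome's markers, default degree 2 — is
#' evaluated at each marker, and the rate is the fit's first derivative
#' there. Negative rates are retained. Chromosomes with fewer than 10
#' markers get `NA` rates with a warning.
#'
#' @param t A [marey_table()] (reverse inversions first; see
#'   [reverse_within_inversions()]).
#' @param span Local-regression span (default 0.7).
#' @param degree Local polynomial degree (default 2).
#' @return data.frame: `marker`, `chrom`, `pos_bp`, `rate_cm_per_mb`.
#' @export
local_recomb_rate <- function(t, span = 0.7, degree = 2) {
  out <- t[, c("marker", "chrom", "pos_bp")]
  out$rate_cm_per_mb <- NA_real_
  for (nm in unique(t$chrom)) {
    sel <- which(t$chrom == nm)
    if (length(sel) < 10) {
      warning("chromosome ", nm, " has < 10 markers; rates set NA")
      next
    }
    mb <- t$pos_bp[sel] / 1e6
    cm <- t$pos_cm[sel]
    out$rate_cm_per_mb[sel] <- vapply(
      mb, function(x0) local_slope(mb, cm, x0, span, degree), numeric(1))
  }
  out
}

#' Protein-coding gene density in physical windows
#'
#' Counts genes per half-open window `[k*w, (k+1)*w)` per chromosome; a gene
#' belongs to the window containing its start coordinate. Only records typed
#' `gene` whose biotype (if annotated) is `protein_coding` are counted.
#'
#' @param annotation A GFF3 file path, or a data.frame with columns `chrom`,
#'   `start`, `type` and optionally `biotype`.
#' @param window_bp Window size (default 500 kb).
#' @return data.frame: `chrom`, `start` (0-based window start), `n_genes`.
#' @export
gene_density <- function(annotation, window_bp = 500000) {
  if (is.character(annotation)) {
    gr <- rtracklayer::import(annotation, format = "gff3")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     type = as.character(gr$type),
                     stringsAsFactors = FALSE)
    df$biotype <- if (!is.null(gr$gene_biotype))
      as.character(gr$gene_biotype) else NA_character_
  } else df <- annotation
  bad <- is.na(df$start) | is.na(df$chrom) | df$start < 1
  if (any(bad)) {
    message(sum(bad), " malformed annotation record(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  genes <- df[df$type == "gene" &
                (is.na(df$biotype) | df$biotype == "protein_coding"), ,
              drop = FALSE]
  out <- list()
  for (nm in unique(genes$chrom)) {
    st <- genes$start[genes$chrom == nm]
    win <- floor(st / window_bp)  # 1-based starts; window [k*w, (k+1)*w)
    tab <- table(win)
    all_win <- 0:max(win)
    cnt <- integer(length(all_win))
    cnt[match(as.integer(names(tab)), all_win)] <- as.integer(tab)
    out[[nm]] <- data.frame(chrom = nm, start = all_win * window_bp,
                            n_genes = cnt, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regress local recombination rate on gene density
#'
#' Pairs each marker's rate with the gene count of its containing window and
#' fits an ordinary least-squares regression of rate on density. Before
#' fitting, markers are excluded if their rate is negative AND its absolute
#' deviation from the chromosome's median rate exceeds `mad_k` times the
#' chromosome's median absolute deviation (markers that do not follow the
#' pattern of their neighbours and would skew rates negative).
#'
#' @param rates Output of [local_recomb_rate()].
#' @param densities Output of [gene_density()].
#' @param window_bp Window size used for `densities`.
#' @param mad_k Outlier multiple (default 3).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_markers_used`, `excluded` (marker ids), `data` (the regression
#'   frame).
#' @export
rate_density_regression <- function(rates, densities, window_bp = 500000,
                                    mad_k = 3) {
  df <- rates[!is.na(rates$rate_cm_per_mb), , drop = FALSE]
  df$win <- floor(df$pos_bp / window_bp) * window_bp
  key <- paste(df$chrom, df$win)
  dkey <- paste(densities$chrom, densities$start)
  df$density <- densities$n_genes[match(key, dkey)]
  df <- df[!is.na(df$density), , drop = FALSE]
  excl <- character(0)
  for (nm in unique(df$chrom)) {
    sel <- df$chrom == nm
    r <- df$rate_cm_per_mb[sel]
    med <- stats::median(r)
    md <- stats::mad(r)
    out <- r < 0 & abs(r - med) > mad_k * max(md, 1e-12)
    excl <- c(excl, df$marker[sel][out])
  }
  df2 <- df[!df$marker %in% excl, , drop = FALSE]
  if (nrow(df2) < 3) stop("fewer than 3 points for regression")
  fit <- stats::lm(rate_cm_per_mb ~ density, data = df2)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n_markers_used = nrow(df2), excluded = excl, data = df2)
}
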