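# Male/female coverage comparison along the X. On a female reference, reads
# from a degenerate (hemizygous) region arrive only from the female's two X
# copies, so the male:female depth ratio drops toward 0.5 there; where the
# neo-Y still resembles the neo-X, male neo-Y reads map onto the X and the
# ratio stays near 1.

#' Windowed, normalized sequencing depth
#'
#' Computes mean depth per half-open window `[k*w, (k+1)*w)` per chromosome
#' and normalizes every window by the sample's mean autosomal windowed depth
#' (so autosomal windows average ~1).
#'
#' @param depth data.frame: `chrom`, `pos` (1-based position or 0-based
#'   window start) or `start`, `depth`. Pre-binned input (one row per
#'   window) is averaged the same way.
#' @param window_bp Window size (default 50 kb).
#' @param x_chrom X chromosome label.
#' @return data.frame: `chrom`, `start` (0-based), `mean_depth`,
#'   `normalized_depth`.
#' @export
window_coverage <- function(depth, window_bp = 50000, x_chrom = "X") {
  pos <- if ("pos" %in% names(depth)) depth$pos - 1 else depth$start
  win <- floor(pos / window_bp) * window_bp
  agg <- stats::aggregate(depth$depth,
                          list(chrom = depth$chrom, start = win), mean)
  names(agg)[3] <- "mean_depth"
  agg <- agg[order(match(agg$chrom, unique(depth$chrom)), agg$start), ]
  auto <- agg$chrom != x_chrom
  if (!any(auto) || mean(agg$mean_depth[auto]) <= 0)
    stop("zero autosomal coverage; cannot normalize")
  agg$normalized_depth <- agg$mean_depth / mean(agg$mean_depth[auto])
  rownames(agg) <- NULL
  agg
}

#' Stratify a chromosome by male/female coverage ratio
#'
#' Labels each window by the male:female normalized-depth ratio —
#' `hemizygous` at or below `thresholds[1]`, `similar` at or above
#' `thresholds[2]`, `intermediate` between — smooths label runs shorter than
#' `min_run` windows into the longer flanking run's label, and merges
#' contiguous same-label windows into segments.
#'
#' @param male_windows,female_windows Outputs of [window_coverage()] for the
#'   two samples (same window grid).
#' @param chrom Chromosome to stratify (default `"X"`).
#' @param thresholds `c(hemizygous_max, similar_min)` ratio cutoffs.
#' @param min_run Minimum run length in windows.
#' @param window_bp Window size.
#' @return data.frame: `chrom`, `start_bp`, `end_bp` (0-based half-open),
#'   `class`, `mean_ratio`. Segments partition the analyzed windows.
#' @export
classify_strata <- function(male_windows, female_windows, chrom = "X",
                            thresholds = c(0.6, 0.85), min_run = 5,
                            window_bp = 50000) {
  m <- male_windows[male_windows$chrom == chrom, , drop = FALSE]
  f <- female_windows[female_windows$chrom == chrom, , drop = FALSE]
  if (!identical(m$start, f$start)) stop("mismatched window grids")
  ratio <- m$normalized_depth / f$normalized_depth
  lab <- ifelse(ratio <= thresholds[1], "hemizygous",
                ifelse(ratio >= thresholds[2], "similar", "intermediate"))
  # merge short runs into the longer flanking run's label
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run)
    if (!length(short)) break
    j <- short[which.min(r$lengths[short])]
    left_len <- if (j > 1) r$lengths[j - 1] else -1L
    right_len <- if (j < length(r$lengths)) r$lengths[j + 1] else -1L
    new_lab <- if (left_len >= right_len) r$values[j - 1] else r$values[j + 1]
    idx0 <- sum(r$lengths[seq_len(j - 1)])
    lab[(idx0 + 1):(idx0 + r$lengths[j])] <- new_lab
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  data.frame(chrom = chrom,
             start_bp = m$start[starts],
             end_bp = m$start[ends] + window_bp,
             class = r$values,
             mean_ratio = vapply(seq_along(starts), function(k)
               mean(ratio[starts[k]:ends[k]]), numeric(1)),
             stringsAsFactors = FALSE)
}
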