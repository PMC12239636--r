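# Crossover counting: parental-origin haplotype inference on the X, minimal
# (obligate) crossover counts per individual per chromosome, and Wilcoxon
# rank-sum comparisons of transmitted recombination between the sexes.

#' Infer per-marker parental origins
#'
#' On the X, returns each F2's maternal-gamete origin at every marker
#' (males: AA = AZ, BB = UT read directly from hemizygous calls; females:
#' AB = maternal AZ, BB = maternal UT, the paternal X being constitutively
#' UT). Autosomes carry the 3-class genotype sequence directly.
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param chrom Chromosome label.
#' @return A markers x F2 matrix: origins `"AZ"`/`"UT"` on the X, genotype
#'   codes `0/1/2` (as character) on autosomes; `NA` propagated.
#' @export
infer_haplotypes <- function(gm, chrom) {
  rows <- which(gm$markers$chrom == chrom)
  f2 <- gm_f2(gm)
  calls <- gm$calls[rows, f2, drop = FALSE]
  if (chrom == gm$x_chrom) {
    sex <- gm$ind$sex[f2]
    bad <- (sex[col(calls)] == "M" & calls == 1L) |
      (sex[col(calls)] == "F" & calls == 2L)
    if (any(bad, na.rm = TRUE))
      stop("impossible X genotype codes present; run QC first")
    out <- vapply(seq_len(ncol(calls)), function(j) {
      o <- x_gamete_origin(calls[, j], rep(sex[j], nrow(calls)))
      ifelse(is.na(o), NA_character_, ifelse(o == "A", "AZ", "UT"))
    }, character(nrow(calls)))
    out <- matrix(out, nrow(calls),
                  dimnames = list(marker_names(gm)[rows], gm$ind$id[f2]))
  } else {
    out <- matrix(as.character(calls), nrow(calls),
                  dimnames = list(marker_names(gm)[rows], gm$ind$id[f2]))
  }
  out
}

#' Minimal crossover count of one sequence
#'
#' The smallest number of crossovers consistent with the non-missing entries.
#' Origin sequences (X) count transitions between consecutive differing
#' origins. Autosomal genotype sequences (codes 0/1/2) count obligate events
#' between consecutive non-missing genotypes: a homozygote-to-opposite-
#' homozygote step forces 2 (one on each gamete), homozygote-to-heterozygote
#' forces 1, equal codes force 0 — which sums to the exhaustive minimum over
#' gamete assignments.
#'
#' @param seq_codes Character vector: origins (`"AZ"`/`"UT"`) or genotype
#'   codes (`"0"`/`"1"`/`"2"`); `NA` skipped.
#' @return Integer count, or `NA` for an all-missing sequence.
#' @export
count_crossovers <- function(seq_codes) {
  v <- seq_codes[!is.na(seq_codes)]
  if (length(v) == 0) return(NA_integer_)
  if (length(v) == 1) return(0L)
  if (all(v %in% c("AZ", "UT"))) {
    return(sum(v[-1] != v[-length(v)]))
  }
  g <- as.integer(v)
  sum(abs(diff(g)))
}

#' Crossover counts for all F2s on one chromosome
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param chrom Chromosome label.
#' @param region Optional `c(start_bp, end_bp)`: markers outside are dropped
#'   before counting.
#' @return data.frame: `id`, `sex`, `chrom`, `count`.
#' @export
crossover_counts <- function(gm, chrom, region = NULL) {
  hap <- infer_haplotypes(gm, chrom)
  if (!is.null(region)) {
    pos <- gm$markers$pos[gm$markers$chrom == chrom]
    keep <- pos >= region[1] & pos <= region[2]
    if (!any(keep)) stop("empty region")
    hap <- hap[keep, , drop = FALSE]
  }
  f2 <- gm_f2(gm)
  data.frame(id = gm$ind$id[f2], sex = gm$ind$sex[f2], chrom = chrom,
             count = apply(hap, 2, count_crossovers),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare crossover counts between the sexes
#'
#' Per chromosome, a two-sided Wilcoxon rank-sum test of female versus male
#' counts (normal approximation with tie correction); the reported W is the
#' Mann-Whitney statistic of the female sample. P-values are
#' Bonferroni-corrected over `n_tests` linkage groups.
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param chromosomes Chromosomes to test (default: all).
#' @param n_tests Bonferroni factor (default 12).
#' @param include_total Append a `"total"` row testing each individual's
#'   crossover count summed over all chromosomes (reported unadjusted, since
#'   it is not part of the per-group family of tests).
#' @return data.frame: `chrom`, `mean_f`, `se_f`, `mean_m`, `se_m`,
#'   `w_statistic`, `p_raw`, `p_adjusted`.
#' @export
compare_sexes <- function(gm, chromosomes = NULL, n_tests = 12,
                          include_total = FALSE) {
  if (is.null(chromosomes)) chromosomes <- unique(gm$markers$chrom)
  rows <- lapply(chromosomes, function(nm) {
    cnt <- crossover_counts(gm, nm)
    f <- cnt$count[cnt$sex == "F" & !is.na(cnt$count)]
    m <- cnt$count[cnt$sex == "M" & !is.na(cnt$count)]
    if (!length(f) || !length(m))
      return(data.frame(chrom = nm, mean_f = NA, se_f = NA, mean_m = NA,
                        se_m = NA, w_statistic = NA, p_raw = NA,
                        p_adjusted = NA))
    wt <- suppressWarnings(
      stats::wilcox.test(f, m, exact = FALSE, correct = FALSE))
    data.frame(chrom = nm,
               mean_f = mean(f), se_f = stats::sd(f) / sqrt(length(f)),
               mean_m = mean(m), se_m = stats::sd(m) / sqrt(length(m)),
               w_statistic = unname(wt$statistic), p_raw = wt$p.value,
               p_adjusted = min(1, n_tests * wt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (include_total) {
    tot <- Reduce(`+`, lapply(chromosomes, function(nm) {
      cc <- crossover_counts(gm, nm)$count
      ifelse(is.na(cc), 0L, cc)
    }))
    sex <- gm$ind$sex[gm_f2(gm)]
    f <- tot[sex == "F"]; m <- tot[sex == "M"]
    wt <- suppressWarnings(
      stats::wilcox.test(f, m, exact = FALSE, correct = FALSE))
    out <- rbind(out, data.frame(
      chrom = "total", mean_f = mean(f), se_f = stats::sd(f) / sqrt(length(f)),
      mean_m = mean(m), se_m = stats::sd(m) / sqrt(length(m)),
      w_statistic = unname(wt$statistic), p_raw = wt$p.value,
      p_adjusted = wt$p.value, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Region-restricted crossover counts and sex comparison
#'
#' Restricts the X (or any chromosome) to a physical region before counting:
#' `exclude_prefix` drops the first `a` bp, `ancestral_only` keeps markers
#' from `a` bp onward, `window` keeps `[a, b]`.
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param chrom Chromosome (default the X).
#' @param mode `"exclude_prefix"`, `"ancestral_only"`, or `"window"`.
#' @param a,b Region parameters in bp (defaults: 25 Mb prefix, 48 Mb
#'   ancestral start).
#' @param n_tests Bonferroni factor for the comparison.
#' @return List: `counts` (per-individual) and `comparison` (one-row table).
#' @export
region_restricted_counts <- function(gm, chrom = NULL,
                                     mode = c("exclude_prefix",
                                              "ancestral_only", "window"),
                                     a = NULL, b = NULL, n_tests = 12) {
  mode <- match.arg(mode)
  if (is.null(chrom)) chrom <- gm$x_chrom
  max_pos <- max(gm$markers$pos[gm$markers$chrom == chrom])
  region <- switch(mode,
                   exclude_prefix = c(if (is.null(a)) 25e6 else a, Inf),
                   ancestral_only = c(if (is.null(a)) 48e6 else a, Inf),
                   window = c(a, b))
  region[2] <- min(region[2], max_pos)
  cnt <- crossover_counts(gm, chrom, region = region)
  f <- cnt$count[cnt$sex == "F" & !is.na(cnt$count)]
  m <- cnt$count[cnt$sex == "M" & !is.na(cnt$count)]
  wt <- suppressWarnings(
    stats::wilcox.test(f, m, exact = FALSE, correct = FALSE))
  comp <- data.frame(chrom = chrom, region_start = region[1],
                     region_end = region[2],
                     mean_f = mean(f), mean_m = mean(m),
                     n_f_recombinant = sum(f >= 1), n_f = length(f),
                     n_m_recombinant = sum(m >= 1), n_m = length(m),
                     w_statistic = unname(wt$statistic), p_raw = wt$p.value,
                     p_adjusted = min(1, n_tests * wt$p.value),
                     stringsAsFactors = FALSE)
  list(counts = cnt, comparison = comp)
}

#' Haplotype frequency among non-recombinant males
#'
#' Among males with zero crossovers inside `region`, tallies the transmitted
#' origin and tests the counts against equal transmission (two-sided exact
#' binomial).
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param chrom Chromosome (default the X).
#' @param region `c(start_bp, end_bp)` (default: whole chromosome).
#' @return List: `n_az`, `n_ut`, `p_value`.
#' @export
haplotype_frequency <- function(gm, chrom = NULL, region = NULL) {
  if (is.null(chrom)) chrom <- gm$x_chrom
  if (is.null(region)) region <- c(0, Inf)
  hap <- infer_haplotypes(gm, chrom)
  pos <- gm$markers$pos[gm$markers$chrom == chrom]
  keep <- pos >= region[1] & pos <= region[2]
  hap <- hap[keep, , drop = FALSE]
  f2 <- gm_f2(gm)
  males <- which(gm$ind$sex[f2] == "M")
  n_az <- n_ut <- 0L
  for (j in males) {
    v <- hap[!is.na(hap[, j]), j]
    if (!length(v) || any(v != v[1])) next  # recombinant or uninformative
    if (v[1] == "AZ") n_az <- n_az + 1L else n_ut <- n_ut + 1L
  }
  p <- if (n_az + n_ut > 0)
    stats::binom.test(n_az, n_az + n_ut, 0.5)$p.value else NA_real_
  list(n_az = n_az, n_ut = n_ut, p_value = p)
}
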