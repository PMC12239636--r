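# Filter cascade turning raw genotype calls into the analysis-ready marker
# set. The fixed order is: call quality -> parental-informative sites (with
# chromosome restriction) -> marker missingness -> individual missingness ->
# thinning -> X-impossible-genotype flags -> segregation distortion.

#' Filter calls on genotype quality and depth
#'
#' Calls failing `GQ > gq_min` or `DP > dp_min` (strict inequalities) are set
#' missing; non-biallelic and indel sites are dropped. If DP/GQ fields are
#' absent the call-level filter is skipped with a warning.
#'
#' @param gm A [geno_matrix()].
#' @param gq_min,dp_min Strict lower cutoffs (defaults 30 and 20).
#' @return Filtered `geno_matrix`.
#' @export
filter_call_quality <- function(gm, gq_min = 30, dp_min = 20) {
  base <- c("A", "C", "G", "T")
  biallelic <- gm$markers$ref %in% base & gm$markers$alt %in% base &
    !grepl(",", gm$markers$alt, fixed = TRUE)
  gm <- gm_subset(gm, markers = which(biallelic))
  if (is.null(gm$gq) && is.null(gm$dp)) {
    warning("no DP/GQ fields; call-quality filter is the identity")
    return(gm)
  }
  fail <- matrix(FALSE, nrow(gm$calls), ncol(gm$calls))
  if (!is.null(gm$gq)) fail <- fail | !(gm$gq > gq_min)
  if (!is.null(gm$dp)) fail <- fail | !(gm$dp > dp_min)
  gm$calls[fail] <- NA_integer_
  gm
}

#' Select parental-informative sites and polarize origins
#'
#' Retains sites where both P0 individuals are called, homozygous, and
#' homozygous for different alleles, so every ALT/REF allele can be assigned
#' an AZ or UT parental origin; calls are re-coded to AZ-allele dosage
#' (`polarized = TRUE`). Sites outside `chromosomes` (the named
#' chromosome-level sequences) are dropped.
#'
#' @param gm A `geno_matrix` (unpolarized ALT dosage, or already polarized, in
#'   which case only informativeness/restriction is applied).
#' @param az_id,ut_id Sample ids of the AZ and UT P0 parents.
#' @param chromosomes Chromosome labels to retain (default: all present).
#' @return Polarized, restricted `geno_matrix`.
#' @export
select_informative_sites <- function(gm, az_id = "P0_sire",
                                     ut_id = "P0_dam",
                                     chromosomes = NULL) {
  if (!all(c(az_id, ut_id) %in% gm$ind$id))
    stop("P0 individuals not found: ", az_id, ", ", ut_id)
  az <- gm$calls[, match(az_id, gm$ind$id)]
  ut <- gm$calls[, match(ut_id, gm$ind$id)]
  hom <- !is.na(az) & !is.na(ut) & az %in% c(0L, 2L) & ut %in% c(0L, 2L) &
    az != ut
  keep <- hom
  if (!is.null(chromosomes)) keep <- keep & gm$markers$chrom %in% chromosomes
  gm2 <- gm_subset(gm, markers = which(keep))
  if (!gm$polarized) {
    az_is_alt <- gm2$calls[, match(az_id, gm2$ind$id)] == 2L
    gm2$markers$origin_az_is_alt <- az_is_alt
    flip <- which(!az_is_alt)
    if (length(flip))
      gm2$calls[flip, ] <- 2L - gm2$calls[flip, , drop = FALSE]
    gm2$polarized <- TRUE
  }
  gm2
}

#' Filter markers and individuals by missingness
#'
#' Markers missing in at least `marker_missing_max` of individuals are removed
#' first, then individuals missing at least `individual_missing_max` of the
#' remaining markers (both cutoffs inclusive). With
#' `mode = "count"` the cutoffs are instead minimum absolute counts of
#' non-missing calls: markers with fewer than `marker_min_calls` genotypes and
#' individuals with fewer than `individual_min_calls` calls are removed.
#'
#' @param gm A `geno_matrix`.
#' @param marker_missing_max,individual_missing_max Inclusive missing-fraction
#'   cutoffs (defaults 0.68 and 0.99).
#' @param mode `"fraction"` or `"count"`.
#' @param marker_min_calls,individual_min_calls Count-mode cutoffs (defaults
#'   75 and 100; a marker/individual is kept iff it has at least this many
#'   non-missing calls).
#' @return Filtered `geno_matrix`. P0 individuals are never removed.
#' @export
filter_missingness <- function(gm, marker_missing_max = 0.68,
                               individual_missing_max = 0.99,
                               mode = c("fraction", "count"),
                               marker_min_calls = 75,
                               individual_min_calls = 100) {
  mode <- match.arg(mode)
  f2 <- gm_f2(gm)
  na_mat <- is.na(gm$calls[, f2, drop = FALSE])
  if (mode == "fraction") {
    keep_m <- rowMeans(na_mat) < marker_missing_max
  } else {
    keep_m <- rowSums(!na_mat) >= marker_min_calls
  }
  gm <- gm_subset(gm, markers = which(keep_m))
  f2 <- gm_f2(gm)
  na_mat <- is.na(gm$calls[, f2, drop = FALSE])
  if (mode == "fraction") {
    keep_f2 <- colMeans(na_mat) < individual_missing_max
  } else {
    keep_f2 <- colSums(!na_mat) >= individual_min_calls
  }
  keep_i <- sort(c(setdiff(seq_len(nrow(gm$ind)), f2), f2[keep_f2]))
  gm <- gm_subset(gm, ind = keep_i)
  if (nrow(gm$markers) == 0 || length(gm_f2(gm)) == 0)
    stop("all data filtered")
  gm
}

#' Thin markers to a minimum physical gap
#'
#' Greedy left-to-right per chromosome: the first marker is kept, and each
#' subsequent marker is kept iff its position exceeds the last kept marker's
#' position by at least `min_gap_bp`.
#'
#' @param gm A `geno_matrix`.
#' @param min_gap_bp Minimum gap (default 100 kb: one marker per 100 kb).
#' @return Thinned `geno_matrix`.
#' @export
thin_markers <- function(gm, min_gap_bp = 100000) {
  keep <- logical(nrow(gm$markers))
  for (nm in unique(gm$markers$chrom)) {
    idx <- which(gm$markers$chrom == nm)
    last <- -Inf
    for (i in idx) {
      if (gm$markers$pos[i] - last >= min_gap_bp) {
        keep[i] <- TRUE
        last <- gm$markers$pos[i]
      }
    }
  }
  gm_subset(gm, markers = which(keep))
}

#' Flag cross-impossible X genotypes
#'
#' Under a UT-female x AZ-male P0 cross the F1 sire transmits one
#' non-recombined UT X to daughters, so F2 females cannot be AZ/AZ; F2 males
#' are hemizygous, so they cannot be heterozygous. Every F2 male AB call and
#' every F2 female AA call on the X is flagged. Autosomes are never flagged.
#'
#' @param gm A polarized `geno_matrix`.
#' @return data.frame of flags: `marker` (row index), `id`, `reason`
#'   (`"male_het_X"` or `"female_AZAZ_X"`).
#' @export
flag_impossible_x <- function(gm) {
  if (any(is.na(gm$ind$sex) | !gm$ind$sex %in% c("M", "F")))
    stop("unknown sex for individual(s): ",
         paste(gm$ind$id[is.na(gm$ind$sex) |
                           !gm$ind$sex %in% c("M", "F")], collapse = ", "))
  x_rows <- which(gm_is_x(gm))
  f2 <- gm_f2(gm)
  flags <- list()
  for (j in f2) {
    v <- gm$calls[x_rows, j]
    if (gm$ind$sex[j] == "M") {
      hit <- which(!is.na(v) & v == 1L)
      reason <- "male_het_X"
    } else {
      hit <- which(!is.na(v) & v == 2L)
      reason <- "female_AZAZ_X"
    }
    if (length(hit))
      flags[[length(flags) + 1]] <- data.frame(
        marker = x_rows[hit], id = gm$ind$id[j], reason = reason,
        stringsAsFactors = FALSE)
  }
  if (length(flags) == 0)
    return(data.frame(marker = integer(), id = character(),
                      reason = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Resolve X-impossible flags
#'
#' A marker flagged in two or more individuals would require double crossover
#' events and is treated as low quality: the whole marker is dropped.
#' Remaining single-individual flags are set missing.
#'
#' @param gm A `geno_matrix`.
#' @param flags Output of [flag_impossible_x()].
#' @return Cleaned `geno_matrix`.
#' @export
resolve_flags <- function(gm, flags) {
  if (nrow(flags) == 0) return(gm)
  tab <- table(flags$marker)
  drop_markers <- as.integer(names(tab)[tab >= 2])
  single <- flags[!flags$marker %in% drop_markers, , drop = FALSE]
  for (k in seq_len(nrow(single))) {
    j <- match(single$id[k], gm$ind$id)
    gm$calls[single$marker[k], j] <- NA_integer_
  }
  if (length(drop_markers))
    gm <- gm_subset(gm, markers = setdiff(seq_len(nrow(gm$markers)),
                                          drop_markers))
  gm
}

#' Segregation-distortion filter
#'
#' Chi-square goodness of fit of each autosomal marker's F2 {AA, AB, BB}
#' counts against the Mendelian 1:2:1 expectation (2 df, missing calls
#' excluded); markers with P below `alpha` are dropped. X markers are exempt:
#' male hemizygosity makes homozygous-looking calls over-represented there by
#' design. Markers with fewer than `min_calls` non-missing F2 calls are
#' skipped with a warning.
#'
#' @param gm A `geno_matrix`.
#' @param alpha Significance cutoff (default 0.01).
#' @param min_calls Minimum informative calls to test (default 10).
#' @return Filtered `geno_matrix` with attribute `"seg_pvalues"`.
#' @export
segregation_distortion_filter <- function(gm, alpha = 0.01, min_calls = 10) {
  f2 <- gm_f2(gm)
  is_x <- gm_is_x(gm)
  pvals <- rep(NA_real_, nrow(gm$markers))
  keep <- rep(TRUE, nrow(gm$markers))
  skipped <- 0L
  for (i in which(!is_x)) {
    v <- gm$calls[i, f2]
    v <- v[!is.na(v)]
    if (length(v) < min_calls) { skipped <- skipped + 1L; next }
    obs <- tabulate(v + 1L, 3L)
    expd <- length(v) * c(0.25, 0.5, 0.25)
    stat <- sum((obs - expd)^2 / expd)
    pvals[i] <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
    if (pvals[i] < alpha) keep[i] <- FALSE
  }
  if (skipped > 0)
    warning(skipped, " marker(s) with < ", min_calls,
            " calls skipped by the segregation-distortion test")
  out <- gm_subset(gm, markers = which(keep))
  attr(out, "seg_pvalues") <- pvals[keep]
  out
}

#' Run the full QC cascade
#'
#' Applies, in order: call-quality filter, parental-informative site
#' selection with chromosome restriction, marker then individual missingness
#' filters, physical thinning, X-impossible-genotype flagging and resolution,
#' and the autosomal segregation-distortion filter.
#'
#' @param gm A raw `geno_matrix`.
#' @param az_id,ut_id P0 sample ids.
#' @param chromosomes Chromosome labels to retain.
#' @param gq_min,dp_min,marker_missing_max,individual_missing_max,min_gap_bp,alpha
#'   Stage parameters (see the individual filters).
#' @param missing_mode `"fraction"` or `"count"` (see [filter_missingness()]).
#' @return Filtered, polarized `geno_matrix` with attributes `"qc_report"`
#'   (per-stage marker/individual counts), `"dropped_markers"` (which marker
#'   fell at which stage) and `"x_flags"` (the impossible-X flag records).
#' @export
run_qc <- function(gm, az_id = "P0_sire", ut_id = "P0_dam",
                   chromosomes = NULL, gq_min = 30, dp_min = 20,
                   marker_missing_max = 0.68, individual_missing_max = 0.99,
                   missing_mode = "fraction", min_gap_bp = 100000,
                   alpha = 0.01) {
  report <- list()
  dropped <- list()
  prev_keys <- paste(gm$markers$chrom, gm$markers$pos)
  note <- function(stage, g) {
    keys <- paste(g$markers$chrom, g$markers$pos)
    gone <- setdiff(prev_keys, keys)
    if (length(gone))
      dropped[[stage]] <<- data.frame(marker = gone, stage = stage,
                                      stringsAsFactors = FALSE)
    prev_keys <<- keys
    data.frame(stage = stage, markers = nrow(g$markers),
               individuals = nrow(g$ind), stringsAsFactors = FALSE)
  }
  report[[1]] <- note("input", gm)
  if (!is.null(gm$gq) || !is.null(gm$dp))
    gm <- filter_call_quality(gm, gq_min, dp_min)
  report[[2]] <- note("call_quality", gm)
  gm <- select_informative_sites(gm, az_id, ut_id, chromosomes)
  report[[3]] <- note("informative_sites", gm)
  gm <- filter_missingness(gm, marker_missing_max, individual_missing_max,
                           mode = missing_mode)
  report[[4]] <- note("missingness", gm)
  gm <- thin_markers(gm, min_gap_bp)
  report[[5]] <- note("thinning", gm)
  flags <- flag_impossible_x(gm)
  gm <- resolve_flags(gm, flags)
  report[[6]] <- note("x_flags", gm)
  gm <- suppressWarnings(segregation_distortion_filter(gm, alpha))
  report[[7]] <- note("segregation_distortion", gm)
  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  attr(gm, "qc_report") <- rep_df
  attr(gm, "dropped_markers") <- if (length(dropped))
    do.call(rbind, c(dropped, list(make.row.names = FALSE)))
  else data.frame(marker = character(), stage = character(),
                  stringsAsFactors = FALSE)
  attr(gm, "x_flags") <- flags
  gm
}
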