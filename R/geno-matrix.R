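#' Genotype matrix
#'
#' The pipeline's central container: a markers-by-individuals matrix of F2
#' genotype codes with marker and sample metadata. Calls are stored as allele
#' dosage in `{0, 1, 2, NA}`. When `polarized = TRUE` the dosage counts
#' AZ-origin alleles, so 2 = AA (AZ/AZ), 1 = AB, 0 = BB (UT/UT); hemizygous
#' male X calls appear as 2 or 0. When `polarized = FALSE` (e.g. freshly read
#' from VCF) the dosage counts ALT alleles and `markers$origin_az_is_alt` is
#' unset until [select_informative_sites()] polarizes against the P0 parents.
#'
#' @param markers data.frame: `chrom`, `pos` (1-based bp, strictly increasing
#'   within chromosome), `ref`, `alt`, optionally `origin_az_is_alt`.
#' @param ind data.frame: `id`, `sex` (`"M"`/`"F"`), `generation`
#'   (`"P0"`/`"F1"`/`"F2"`).
#' @param calls Integer matrix, markers x individuals.
#' @param polarized Logical; see above.
#' @param x_chrom Label of the X chromosome.
#' @param dp,gq Optional matrices of per-call depth and genotype quality.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(markers, ind, calls, polarized = FALSE,
                        x_chrom = "X", dp = NULL, gq = NULL) {
  stopifnot(nrow(calls) == nrow(markers), ncol(calls) == nrow(ind))
  if (!all(is.na(calls) | calls %in% 0:2))
    stop("calls must be in {0, 1, 2, NA}")
  for (nm in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == nm]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chromosome ",
           nm)
  }
  colnames(calls) <- ind$id
  structure(list(markers = markers, ind = ind,
                 calls = matrix(as.integer(calls), nrow(calls),
                                dimnames = dimnames(calls)),
                 polarized = isTRUE(polarized), x_chrom = x_chrom,
                 dp = dp, gq = gq),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix: %d markers x %d individuals (%d chromosomes)%s>\n",
    nrow(x$markers), nrow(x$ind), length(unique(x$markers$chrom)),
    if (x$polarized) ", polarized" else ""))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$markers), nrow(x$ind))

#' Subset a genotype matrix
#'
#' @param gm A `geno_matrix`.
#' @param markers Integer/logical index over markers.
#' @param ind Integer/logical index over individuals, or character ids.
#' @return The subsetted `geno_matrix`.
#' @export
gm_subset <- function(gm, markers = NULL, ind = NULL) {
  if (is.null(markers)) markers <- seq_len(nrow(gm$markers))
  if (is.null(ind)) ind <- seq_len(nrow(gm$ind))
  if (is.character(ind)) ind <- match(ind, gm$ind$id)
  gm$markers <- gm$markers[markers, , drop = FALSE]
  rownames(gm$markers) <- NULL
  gm$ind <- gm$ind[ind, , drop = FALSE]
  rownames(gm$ind) <- NULL
  gm$calls <- gm$calls[markers, ind, drop = FALSE]
  if (!is.null(gm$dp)) gm$dp <- gm$dp[markers, ind, drop = FALSE]
  if (!is.null(gm$gq)) gm$gq <- gm$gq[markers, ind, drop = FALSE]
  gm
}

# F2 columns (the mapping panel)
gm_f2 <- function(gm) which(gm$ind$generation == "F2")

# logical vector over markers: on the X?
gm_is_x <- function(gm) gm$markers$chrom == gm$x_chrom
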