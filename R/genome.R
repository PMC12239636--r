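#' Map-function conversions
#'
#' Convert between recombination fraction and additive genetic distance under
#' the Haldane (no interference) or Kosambi map function.
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @param d Genetic distance in centiMorgans.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @return `rf_to_cm()` returns cM; `cm_to_rf()` returns a recombination
#'   fraction.
#' @examples
#' cm_to_rf(rf_to_cm(0.2))
#' @export
rf_to_cm <- function(r, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  r <- pmin(pmax(r, 0), 0.5)
  if (map_function == "haldane") {
    d <- -50 * log(1 - 2 * r)
  } else {
    d <- 25 * log((1 + 2 * r) / (1 - 2 * r))
  }
  d
}

#' @rdname rf_to_cm
#' @export
cm_to_rf <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (map_function == "haldane") {
    0.5 * (1 - exp(-2 * d / 100))
  } else {
    0.5 * tanh(2 * d / 100)
  }
}

#' Chromosome model for simulation
#'
#' A chromosome is described by its physical length, a Marey curve (a monotone
#' non-decreasing piecewise-linear map from physical position in bp to genetic
#' position in cM, with G(0) = 0), and optional structural annotations: an
#' inversion segregating in the cross relative to reference coordinates, and,
#' on the X, the "similar" region where neo-Y reads contaminate male genotype
#' calls.
#'
#' @param name Chromosome label.
#' @param length_bp Physical length in bp.
#' @param marey_bp,marey_cm Knots of the piecewise-linear Marey curve. Must
#'   start at (0, 0), end at `length_bp`, and be non-decreasing in both
#'   coordinates.
#' @param is_x Logical; is this the X chromosome?
#' @param inversion Optional `c(start_bp, end_bp)` interval whose marker order
#'   is reversed in reference coordinates.
#' @param similar_region Optional `c(start_bp, end_bp)` interval on the X where
#'   neo-Y contamination applies.
#' @return An object of class `chrom_model`.
#' @export
chrom_model <- function(name, length_bp, marey_bp, marey_cm, is_x = FALSE,
                        inversion = NULL, similar_region = NULL) {
  stopifnot(length(marey_bp) == length(marey_cm), length(marey_bp) >= 2)
  if (marey_bp[1] != 0 || marey_cm[1] != 0)
    stop("Marey curve must start at (0, 0)")
  if (marey_bp[length(marey_bp)] != length_bp)
    stop("Marey curve must end at length_bp")
  if (any(diff(marey_bp) <= 0) || any(diff(marey_cm) < 0))
    stop("Marey curve must be non-decreasing (bp strictly increasing)")
  if (!is.null(inversion)) {
    stopifnot(length(inversion) == 2, inversion[1] < inversion[2],
              inversion[1] >= 0, inversion[2] <= length_bp)
  }
  structure(list(name = as.character(name), length_bp = as.numeric(length_bp),
                 marey_bp = as.numeric(marey_bp),
                 marey_cm = as.numeric(marey_cm),
                 is_x = isTRUE(is_x), inversion = inversion,
                 similar_region = similar_region),
            class = "chrom_model")
}

#' @export
print.chrom_model <- function(x, ...) {
  cat(sprintf("<chrom_model %s: %.1f Mb, %.1f cM%s%s>\n", x$name,
              x$length_bp / 1e6, chrom_map_length(x),
              if (x$is_x) ", X" else "",
              if (!is.null(x$inversion))
                sprintf(", inversion %.1f-%.1f Mb", x$inversion[1] / 1e6,
                        x$inversion[2] / 1e6) else ""))
  invisible(x)
}

#' Total map length of a chromosome model
#' @param chrom A `chrom_model`.
#' @return Map length in cM.
#' @export
chrom_map_length <- function(chrom) {
  chrom$marey_cm[length(chrom$marey_cm)]
}

# bp -> cM along the Marey curve (vectorized)
marey_bp_to_cm <- function(chrom, bp) {
  stats::approx(chrom$marey_bp, chrom$marey_cm, xout = bp, rule = 2)$y
}

# cM -> bp by inverting the Marey curve; on flat (zero-recombination)
# stretches the inverse is set-valued and the left endpoint is returned.
marey_cm_to_bp <- function(chrom, cm) {
  stats::approx(chrom$marey_cm, chrom$marey_bp, xout = cm, rule = 2,
                ties = "min")$y
}

#' Default 12-chromosome genome for the simulator
#'
#' Eleven autosomes plus one X chromosome. The X is 64.7 Mb with a
#' recombination-suppressed interior from 26 to 48 Mb (metacentric,
#' pericentromeric); autosomes are acro/telocentric with suppression at one
#' end. Map lengths are proportioned after the per-chromosome crossover means
#' of a mountain pine beetle F2 intercross and scaled so the genome totals
#' 1069.2 cM (mean linkage-group length 89.1 cM). The X carries a segregating
#' 18 Mb inversion (40.0-58.0 Mb in reference coordinates) and a neo-Y
#' "similar" region over its first 26 Mb; smaller inversions sit on
#' chromosomes 2 (3.7 Mb) and 3 (5.5 Mb).
#'
#' @param total_cm Total genome map length in cM.
#' @param x_inversion Logical; place the 18 Mb inversion on the X.
#' @param autosome_inversions Logical; place the chromosome 2 and 3 inversions.
#' @return A named list of `chrom_model` objects, X last.
#' @export
default_genome <- function(total_cm = 1069.2, x_inversion = TRUE,
                           autosome_inversions = TRUE) {
  # relative map lengths ~ 100 * mean transmitted crossovers per chromosome
  rel <- c(`1` = 98, `2` = 87, `3` = 175, `4` = 130, `5` = 108, `6` = 56,
           `7` = 83, `8` = 59, `9` = 78, `10` = 82, `11` = 73, X = 130)
  cm <- rel / sum(rel) * total_cm
  bp <- c(`1` = 48e6, `2` = 44e6, `3` = 60e6, `4` = 52e6, `5` = 46e6,
          `6` = 30e6, `7` = 38e6, `8` = 31e6, `9` = 36e6, `10` = 37e6,
          `11` = 33e6, X = 64.7e6)
  genome <- vector("list", 12)
  names(genome) <- names(rel)
  for (nm in setdiff(names(rel), "X")) {
    L <- bp[[nm]]; M <- cm[[nm]]
    inv <- NULL
    if (autosome_inversions && nm == "2") inv <- c(20e6, 23.7e6)
    if (autosome_inversions && nm == "3") inv <- c(30e6, 35.5e6)
    # telocentric: pericentromeric 35% of the chromosome carries 3% of the map
    genome[[nm]] <- chrom_model(nm, L,
                                marey_bp = c(0, 0.35 * L, L),
                                marey_cm = c(0, 0.03 * M, M),
                                inversion = inv)
  }
  Lx <- bp[["X"]]; Mx <- cm[["X"]]
  genome[["X"]] <- chrom_model("X", Lx,
                               marey_bp = c(0, 26e6, 48e6, Lx),
                               marey_cm = c(0, 0.44 * Mx, 0.56 * Mx, Mx),
                               is_x = TRUE,
                               inversion = if (x_inversion) c(40e6, 58e6),
                               similar_region = c(0, 26e6))
  genome
}

#' Place markers along a genome
#'
#' Draws marker positions per chromosome, allocating the total in proportion
#' to physical length, with positions uniform on the chromosome, de-duplicated
#' and sorted. With `spacing_bp` set, markers are instead laid on a jittered
#' regular grid (roughly one marker per `spacing_bp`).
#'
#' @param genome List of `chrom_model` objects.
#' @param n_markers Total number of markers across the genome.
#' @param spacing_bp Optional target spacing; overrides `n_markers`.
#' @return A data.frame with columns `chrom`, `pos` (reference bp, sorted
#'   within chromosome).
#' @export
place_markers <- function(genome, n_markers = 822, spacing_bp = NULL) {
  lens <- vapply(genome, function(g) g$length_bp, numeric(1))
  out <- lapply(names(genome), function(nm) {
    L <- genome[[nm]]$length_bp
    if (is.null(spacing_bp)) {
      k <- max(2L, round(n_markers * L / sum(lens)))
      pos <- sort(unique(round(stats::runif(k, 1, L))))
    } else {
      grid <- seq(spacing_bp / 2, L, by = spacing_bp)
      pos <- sort(unique(pmin(L, pmax(1, round(
        grid + stats::runif(length(grid), -0.3, 0.3) * spacing_bp)))))
    }
    data.frame(chrom = nm, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# true physical position of a marker: reference positions inside a segregating
# inversion are reflected about the inversion interval
true_marker_pos <- function(chrom, ref_pos) {
  pos <- ref_pos
  if (!is.null(chrom$inversion)) {
    inside <- ref_pos >= chrom$inversion[1] & ref_pos <= chrom$inversion[2]
    pos[inside] <- chrom$inversion[1] + chrom$inversion[2] - ref_pos[inside]
  }
  pos
}
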