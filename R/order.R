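# Marker-order validation against the reference assignment. Linkage groups
# follow reference chromosomes; within a chromosome, single-marker relocation
# hill-climbing shortens the chained two-point map, and markers whose
# strongest linkage is to another chromosome are removed.

# chained two-point Haldane length of an order (indices into the rf matrix)
chained_length <- function(rf_mat, ord) {
  if (length(ord) < 2) return(0)
  r <- rf_mat[cbind(ord[-length(ord)], ord[-1])]
  r[is.na(r)] <- 0.499
  sum(rf_to_cm(pmin(r, 0.499)))
}

#' Validate and repair marker order
#'
#' Starting from physical order within each reference chromosome, markers
#' whose strongest inter-chromosome linkage LOD exceeds their strongest
#' intra-chromosome LOD are removed (probable mapping errors). Then
#' single-marker relocation hill-climbing runs per chromosome: markers are
#' scanned left to right, each tried at every other position, and a move is
#' accepted only if it strictly reduces the chained two-point Haldane map
#' length; ties keep the current position. Scanning repeats until a full pass
#' makes no move. A second move class — reversing a contiguous block, again
#' accepted only on strict improvement — is interleaved, since segregating
#' inversions present exactly as reversed blocks that single-marker moves
#' unwind poorly; no rippling (windowed exhaustive permutation) is done.
#'
#' Moves are accepted only when they shorten the map by more than
#' `min_improve_cm`: in recombination-suppressed stretches every order is
#' nearly likelihood-equivalent and unthresholded noise-chasing scrambles
#' marker order (occasionally into spurious reversed runs), while genuine
#' misplacements save many cM per move.
#'
#' @param gm A polarized, QC'd [geno_matrix()].
#' @param max_passes Safety cap on hill-climbing passes.
#' @param min_improve_cm Minimum map-length reduction (cM) to accept a move.
#' @return List: `order` (per-chromosome integer marker row indices, map
#'   order), `removed` (row indices of cross-linked markers), `rf`, `lod`
#'   (pairwise matrices).
#' @export
order_and_validate <- function(gm, max_passes = 20,
                               min_improve_cm = 1) {
  pw <- est_rf_matrix(gm)
  chroms <- unique(gm$markers$chrom)
  chrom_of <- gm$markers$chrom
  n_mark <- nrow(gm$markers)

  removed <- integer(0)
  for (i in seq_len(n_mark)) {
    same <- which(chrom_of == chrom_of[i])
    same <- setdiff(same, i)
    other <- which(chrom_of != chrom_of[i])
    if (!length(same) || !length(other)) next
    intra <- suppressWarnings(max(pw$lod[i, same], na.rm = TRUE))
    inter <- suppressWarnings(max(pw$lod[i, other], na.rm = TRUE))
    if (is.finite(inter) && (!is.finite(intra) || inter > intra))
      removed <- c(removed, i)
  }

  order <- list()
  for (nm in chroms) {
    ord <- setdiff(which(chrom_of == nm), removed)
    if (length(ord) > 2) {
      for (pass in seq_len(max_passes)) {
        moved <- FALSE
        # segment reversals first: they unwind inversions in one move
        repeat {
          res <- best_reversal(pw$rf, ord, min_improve_cm)
          if (is.null(res)) break
          ord <- res
          moved <- TRUE
        }
        for (pos in seq_along(ord)) {
          cur_len <- chained_length(pw$rf, ord)
          mk <- ord[pos]
          rest <- ord[-pos]
          best_len <- cur_len
          best_ord <- ord
          for (ins in 0:length(rest)) {
            cand <- append(rest, mk, after = ins)
            if (identical(cand, ord)) next
            len <- chained_length(pw$rf, cand)
            if (len < best_len - min_improve_cm) {
              best_len <- len
              best_ord <- cand
            }
          }
          if (!identical(best_ord, ord)) {
            ord <- best_ord
            moved <- TRUE
          }
        }
        if (!moved) break
      }
    }
    order[[nm]] <- ord
  }
  list(order = order, removed = removed, rf = pw$rf, lod = pw$lod)
}

# best strictly-improving contiguous-block reversal, or NULL. Reversing
# ord[i..j] only changes the two boundary adjacencies, so each candidate is
# scored in O(1) from the chained-length deltas.
best_reversal <- function(rf_mat, ord, min_improve_cm = 1) {
  K <- length(ord)
  d <- function(a, b) {
    r <- rf_mat[a, b]
    if (is.na(r)) r <- 0.499
    rf_to_cm(min(r, 0.499))
  }
  best_delta <- -min_improve_cm
  best <- NULL
  for (i in 1:(K - 1)) {
    for (j in (i + 1):K) {
      delta <- 0
      if (i > 1) delta <- delta + d(ord[i - 1], ord[j]) - d(ord[i - 1], ord[i])
      if (j < K) delta <- delta + d(ord[i], ord[j + 1]) - d(ord[j], ord[j + 1])
      if (delta < best_delta) {
        best_delta <- delta
        best <- c(i, j)
      }
    }
  }
  if (is.null(best)) return(NULL)
  i <- best[1]; j <- best[2]
  c(ord[seq_len(i - 1)], rev(ord[i:j]), if (j < K) ord[(j + 1):K])
}
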