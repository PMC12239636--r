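# File formats. Coordinates: VCF- and GFF3-derived tables are 1-based
# inclusive; BED and window outputs are 0-based half-open.

#' Write genotypes as VCF 4.2
#'
#' Emits GT (plus DP/GQ when present). Polarized AZ-dosage calls are
#' converted back to ALT dosage through each marker's `origin_az_is_alt`
#' flag, so write-then-read round-trips the GT field exactly.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  mk <- gm$markers
  az_is_alt <- if (!is.null(mk$origin_az_is_alt)) mk$origin_az_is_alt
               else rep(TRUE, nrow(mk))
  calls <- gm$calls
  if (gm$polarized) {
    flip <- which(!az_is_alt)
    if (length(flip)) calls[flip, ] <- 2L - calls[flip, , drop = FALSE]
  }
  gt <- matrix(c("0/0", "0/1", "1/1")[calls + 1L], nrow(calls))
  gt[is.na(calls)] <- "./."
  has_fmt <- !is.null(gm$dp) && !is.null(gm$gq)
  if (has_fmt) {
    gt <- matrix(paste0(gt, ":", ifelse(is.na(gm$dp), ".", gm$dp), ":",
                        ifelse(is.na(gm$gq), ".", gm$gq)), nrow(gt))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=neoxmap",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_fmt)
    hdr <- c(hdr,
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
             '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  for (nm in unique(mk$chrom))
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", nm))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$ind$id),
                      collapse = "\t"))
  body <- paste(mk$chrom, mk$pos, paste0(mk$chrom, "_", mk$pos), mk$ref,
                mk$alt, ".", "PASS", ".",
                if (has_fmt) "GT:DP:GQ" else "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genotype VCF with its sample sheet
#'
#' Loads GT (and DP/GQ when present) via vcfR. Multiallelic records are
#' excluded and counted in the `"n_multiallelic"` attribute; calls return
#' unpolarized (ALT dosage) until [select_informative_sites()] assigns
#' parental origins.
#'
#' @param path VCF path.
#' @param sample_sheet data.frame (`id`, `sex`, `generation`) or TSV path.
#' @param x_chrom X chromosome label.
#' @return An unpolarized [geno_matrix()].
#' @export
read_genotype_vcf <- function(path, sample_sheet, x_chrom = "X") {
  if (is.character(sample_sheet))
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)
  missing_s <- setdiff(samples, sample_sheet$id)
  if (length(missing_s))
    stop("VCF sample(s) absent from sample sheet: ",
         paste(missing_s, collapse = ", "))
  keep <- which(!multi)
  gt <- gt_raw[keep, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  dp <- gq <- NULL
  fmts <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DP" %in% fmts)
    dp <- apply(vcfR::extract.gt(v, "DP")[keep, , drop = FALSE], 2,
                as.numeric)
  if ("GQ" %in% fmts)
    gq <- apply(vcfR::extract.gt(v, "GQ")[keep, , drop = FALSE], 2,
                as.numeric)
  mk <- data.frame(chrom = fix[keep, "CHROM"],
                   pos = as.numeric(fix[keep, "POS"]),
                   ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                   stringsAsFactors = FALSE)
  ind <- sample_sheet[match(samples, sample_sheet$id), , drop = FALSE]
  out <- geno_matrix(mk, ind, dos, polarized = FALSE, x_chrom = x_chrom,
                     dp = dp, gq = gq)
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Write / read a genetic map TSV
#'
#' Columns `chrom`, `marker`, `pos_bp`, `pos_cm`; 1-based inclusive bp. The
#' exchange format between the map, scan, Marey and crossover stages.
#'
#' @param map A `genetic_map` (or compatible data.frame).
#' @param path TSV path.
#' @return `write_map_tsv()`: the path, invisibly. `read_map_tsv()`: a
#'   `genetic_map`.
#' @export
write_map_tsv <- function(map, path) {
  con <- file(path, "w")
  writeLines("# genetic map; pos_bp 1-based inclusive; pos_cm per linkage group",
             con)
  utils::write.table(as.data.frame(map)[, c("chrom", "marker", "pos_bp",
                                            "pos_cm")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_map_tsv
#' @param x_chrom X chromosome label.
#' @param map_function Map function label to attach.
#' @export
read_map_tsv <- function(path, x_chrom = "X", map_function = "haldane") {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  lengths <- tapply(df$pos_cm, df$chrom, max)[unique(df$chrom)]
  structure(df, lengths = lengths, total_cm = sum(lengths),
            x_chrom = x_chrom, map_function = map_function,
            class = c("genetic_map", "data.frame"))
}

#' Write a sample sheet / phenotype table
#' @param df data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write truth records of a simulated dataset as JSON
#' @param sim A `sim_dataset`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(sim, path) {
  tr <- sim$truth
  mos_df <- function(m) if (is.null(m)) NULL else as.data.frame(m)
  out <- list(
    seed = tr$seed,
    x_chrom = tr$x_chrom,
    qtl = unclass(tr$qtl),
    inversions = tr$inversions[!vapply(tr$inversions, is.null, logical(1))],
    qtl_origin = as.list(stats::setNames(tr$qtl_origin,
                                         sim$phenotypes$id)),
    maternal = lapply(tr$maternal, function(ch) lapply(ch, mos_df)),
    paternal = lapply(tr$paternal, function(ch) lapply(ch, mos_df)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
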