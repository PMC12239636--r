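#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> QC -> linkage map (+ sex-specific maps) ->
#' QTL scan with permutation thresholds and Bayes interval -> Marey analysis
#' -> crossover analysis -> coverage stratification (when depth data are
#' supplied), writing each stage's artifacts under `out_dir` (when given)
#' and returning a machine-readable summary.
#'
#' @param vcf,sample_sheet Input VCF and sample-sheet TSV paths; if `NULL`, a
#'   dataset is simulated with `sim_args`.
#' @param pheno Phenotype data.frame or TSV path (`id`, `generation_time`,
#'   `body_size`); taken from the simulation when `NULL`.
#' @param depth Optional depth data.frame or TSV (`sample`, `chrom`,
#'   `start`/`pos`, `depth`) for the coverage stage.
#' @param gff Optional GFF3 path for gene density.
#' @param out_dir Output directory (`NULL` = don't write files).
#' @param seed Top-level seed; per-stage streams use fixed offsets.
#' @param sim_args List of arguments to [simulate_cross()].
#' @param n_perm Permutations for LOD thresholds.
#' @param reorder Run [order_and_validate()] before mapping (default `TRUE`;
#'   physical order is wrong wherever inversions segregate against the
#'   reference).
#' @param error_prob Genotyping-error rate for the HMM stages.
#' @param scan_pheno Trait to scan (`"generation_time"` or `"body_size"`).
#' @param qc_args Extra arguments to [run_qc()].
#' @return List of stage results plus `summary` (also written as JSON).
#' @export
run_pipeline <- function(vcf = NULL, sample_sheet = NULL, pheno = NULL,
                         depth = NULL, gff = NULL, out_dir = NULL, seed = 1,
                         sim_args = list(), n_perm = 1000, reorder = TRUE,
                         error_prob = 0.001,
                         scan_pheno = "generation_time", qc_args = list()) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) if (!is.null(out_dir))
    writer(file.path(out_dir, name))

  # --- data ---------------------------------------------------------------
  sim <- NULL
  if (is.null(vcf)) {
    sim <- do.call(simulate_cross, c(list(seed = seed), sim_args))
    gm_raw <- sim$genotypes
    if (is.null(pheno)) pheno <- sim$phenotypes
    emit("simulated.vcf", function(p) write_genotype_vcf(gm_raw, p))
    emit("samples.tsv", function(p) write_tsv(gm_raw$ind, p))
    emit("phenotypes.tsv", function(p) write_tsv(pheno, p))
    emit("truth.json", function(p) write_truth_json(sim, p))
  } else {
    gm_raw <- read_genotype_vcf(vcf, sample_sheet)
    if (is.character(pheno))
      pheno <- utils::read.delim(pheno, stringsAsFactors = FALSE)
  }

  # --- qc -----------------------------------------------------------------
  gm <- do.call(run_qc, c(list(gm_raw), qc_args))
  emit("filtered.vcf", function(p) write_genotype_vcf(gm, p))
  emit("qc_report.tsv", function(p) write_tsv(attr(gm, "qc_report"), p))
  emit("qc_dropped_markers.tsv", function(p)
    write_tsv(attr(gm, "dropped_markers"), p))

  # --- linkage map --------------------------------------------------------
  ord <- NULL
  if (reorder) {
    ov <- order_and_validate(gm)
    if (length(ov$removed)) {
      kept <- setdiff(seq_len(nrow(gm$markers)), ov$removed)
      gm <- gm_subset(gm, markers = kept)
      ord <- lapply(ov$order, function(o) match(o, kept))
    } else ord <- ov$order
  }
  map <- estimate_map(gm, order = ord, error_prob = error_prob,
                      error_lod_cutoff = 4)
  sex_maps <- sex_specific_maps(gm, order = ord, error_prob = error_prob)
  emit("map.tsv", function(p) write_map_tsv(map, p))
  emit("map_male.tsv", function(p) write_map_tsv(sex_maps$male, p))
  emit("map_female.tsv", function(p) write_map_tsv(sex_maps$female, p))

  # --- qtl scan -----------------------------------------------------------
  y <- stats::setNames(pheno[[scan_pheno]], pheno$id)
  gp <- calc_genoprob(gm, map, step_cm = 1, error_prob = error_prob)
  scan <- scan_em(gm, map, y, genoprob = gp,
                  adjust_sex = scan_pheno == "body_size")
  thr <- permutation_thresholds(gm, map, y, n_perm = n_perm,
                                seed = seed + 1000L, genoprob = gp,
                                adjust_sex = scan_pheno == "body_size")
  peak <- attr(scan, "peak")
  ci <- bayes_interval(scan, peak$chrom)
  emit("scan.tsv", function(p) write_tsv(as.data.frame(scan), p))
  emit("thresholds.json", function(p)
    jsonlite::write_json(thr[c("threshold_auto", "threshold_x",
                               "alpha_auto", "alpha_x")],
                         p, auto_unbox = TRUE, digits = NA))
  emit("effects.tsv", function(p) write_tsv(attr(scan, "effects"), p))

  # --- marey --------------------------------------------------------------
  mt <- marey_table(map)
  inv <- detect_inversions(mt)
  mt_corr <- reverse_within_inversions(mt, inv)
  rates <- suppressWarnings(local_recomb_rate(mt_corr))
  emit("inversions.tsv", function(p) write_tsv(inv, p))
  emit("rates.tsv", function(p) write_tsv(rates, p))
  dens_reg <- NULL
  if (!is.null(gff)) {
    dens <- gene_density(gff)
    dens_reg <- rate_density_regression(rates, dens)
    emit("rate_density.json", function(p)
      jsonlite::write_json(dens_reg[c("slope", "intercept", "r_squared",
                                      "p_value", "n_markers_used")],
                           p, auto_unbox = TRUE, digits = NA))
  }

  # --- crossovers ---------------------------------------------------------
  comp <- compare_sexes(gm)
  x_window <- region_restricted_counts(gm, mode = "window", a = 26.9e6,
                                       b = 49.0e6)
  hapfreq <- haplotype_frequency(gm)
  emit("xo_comparison.tsv", function(p) write_tsv(comp, p))
  hap_x <- infer_haplotypes(gm, gm$x_chrom)
  emit("haplotypes_x.tsv", function(p)
    write_tsv(data.frame(marker = rownames(hap_x), hap_x,
                         check.names = FALSE), p))

  # --- coverage -----------------------------------------------------------
  strata <- NULL
  if (!is.null(depth)) {
    if (is.character(depth))
      depth <- utils::read.delim(depth, stringsAsFactors = FALSE)
    wm <- window_coverage(depth[depth$sample == "male", ])
    wf <- window_coverage(depth[depth$sample == "female", ])
    strata <- classify_strata(wm, wf)
    emit("strata.bed", function(p) {
      con <- file(p, "w")
      writeLines("# 0-based half-open windows", con)
      utils::write.table(strata[, c("chrom", "start_bp", "end_bp", "class")],
                         con, sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      close(con)
      invisible(p)
    })
  }

  summary <- list(
    n_markers = nrow(gm$markers), n_f2 = length(gm_f2(gm)),
    map_lengths_cm = as.list(attr(map, "lengths")),
    total_map_cm = attr(map, "total_cm"),
    male_map_cm = attr(sex_maps$male, "total_cm"),
    female_map_cm = attr(sex_maps$female, "total_cm"),
    peak = as.list(peak[, c("chrom", "pos_cm", "pos_bp", "lod")]),
    threshold_auto = thr$threshold_auto, threshold_x = thr$threshold_x,
    bayes_interval = ci[c("chrom", "cm_lo", "cm_hi", "bp_lo", "bp_hi")],
    inversions = inv[, c("chrom", "start_bp", "end_bp", "n_markers")],
    xo_comparison = comp,
    x_window_26.9_49.0 = x_window$comparison,
    male_haplotype_counts = hapfreq[c("n_az", "n_ut", "p_value")],
    rate_density = if (!is.null(dens_reg))
      dens_reg[c("slope", "r_squared", "p_value")],
    strata = strata, seed = seed)
  emit("summary.json", function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null"))

  invisible(list(sim = sim, genotypes = gm, map = map, sex_maps = sex_maps,
                 scan = scan, thresholds = thr, bayes = ci, marey = mt_corr,
                 inversions = inv, rates = rates, rate_density = dens_reg,
                 xo_comparison = comp, x_window = x_window,
                 haplotype_frequency = hapfreq, strata = strata,
                 summary = summary))
}

#' Marey-map plot
#'
#' @param mt A [marey_table()].
#' @param chroms Chromosomes to draw (default all).
#' @param overlay Optional second map or `marey_table` (e.g. a published
#'   reference map) drawn underneath in grey.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `mt`.
#' @export
plot_marey <- function(mt, chroms = NULL, overlay = NULL, ...) {
  if (is.null(chroms)) chroms <- unique(mt$chrom)
  if (!is.null(overlay)) overlay <- marey_table(overlay, orient_ties = FALSE)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(chroms)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in chroms) {
    sub <- mt[mt$chrom == nm, ]
    graphics::plot(sub$pos_bp / 1e6, sub$pos_cm, type = "n",
                   xlab = "physical position (Mb)",
                   ylab = "genetic position (cM)", main = nm, ...)
    if (!is.null(overlay)) {
      ov <- overlay[overlay$chrom == nm, ]
      graphics::points(ov$pos_bp / 1e6, ov$pos_cm, pch = 16, cex = 0.5,
                       col = "grey70")
    }
    graphics::points(sub$pos_bp / 1e6, sub$pos_cm, pch = 16, cex = 0.6)
  }
  invisible(mt)
}

#' LOD-curve plot
#'
#' @param scan A `scan_result`.
#' @param thresholds Optional list with `threshold_auto` / `threshold_x`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `scan`.
#' @export
plot_scan <- function(scan, thresholds = NULL, ...) {
  chroms <- unique(scan$chrom)
  offs <- 0
  xs <- numeric(0); mids <- numeric(0)
  for (nm in chroms) {
    sub <- scan[scan$chrom == nm, ]
    xs <- c(xs, sub$pos_cm + offs, NA)
    mids <- c(mids, offs + max(sub$pos_cm) / 2)
    offs <- offs + max(sub$pos_cm) + 5
  }
  lods <- unlist(lapply(chroms, function(nm)
    c(scan$lod[scan$chrom == nm], NA)))
  graphics::plot(xs, lods, type = "l", xaxt = "n", xlab = "",
                 ylab = "LOD", ...)
  graphics::axis(1, at = mids, labels = chroms, las = 2)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$threshold_auto, lty = 2)
    graphics::abline(h = thresholds$threshold_x, lty = 2, col = "red")
  }
  invisible(scan)
}
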