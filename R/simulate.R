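# --- haplotype mosaics ------------------------------------------------------

#' Haplotype mosaics
#'
#' An inherited chromosome is represented as an ordered run of
#' parental-origin segments. Segments are stored half-open `(start, end]` in
#' bp, starting at 0 and ending at the chromosome length, so integer positions
#' `1..length_bp` are tiled exactly; adjacent segments differ in origin and
#' internal boundaries are crossover breakpoints.
#'
#' @param length_bp Chromosome length.
#' @param origin `"AZ"` or `"UT"`.
#' @return A data.frame of class `hap_mosaic` with columns `start`, `end`,
#'   `origin`.
#' @export
pure_mosaic <- function(length_bp, origin = c("AZ", "UT")) {
  origin <- match.arg(origin)
  structure(data.frame(start = 0, end = as.numeric(length_bp),
                       origin = origin, stringsAsFactors = FALSE),
            class = c("hap_mosaic", "data.frame"))
}

#' Parental origin at physical positions
#' @param mosaic A `hap_mosaic`.
#' @param pos Vector of positions in bp (in `(0, length_bp]`).
#' @return Character vector of origins.
#' @export
mosaic_origin_at <- function(mosaic, pos) {
  idx <- 1L + findInterval(pos - 1e-9, mosaic$end)
  idx <- pmin(idx, nrow(mosaic))
  mosaic$origin[idx]
}

#' Crossover count of a mosaic
#' @param mosaic A `hap_mosaic`.
#' @return Number of internal breakpoints.
#' @export
mosaic_n_crossovers <- function(mosaic) nrow(mosaic) - 1L

# merge adjacent same-origin segments
mosaic_simplify <- function(segs) {
  keep <- c(TRUE, segs$origin[-1] != segs$origin[-nrow(segs)])
  grp <- cumsum(keep)
  out <- data.frame(start = tapply(segs$start, grp, min),
                    end = tapply(segs$end, grp, max),
                    origin = segs$origin[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("hap_mosaic", "data.frame"))
}

#' Simulate one meiosis
#'
#' Draws a gamete from a parent's two chromosome copies. The crossover count
#' is Poisson with mean equal to the chromosome's map length in Morgans (no
#' interference, consistent with the Haldane map function); crossover
#' positions are drawn uniformly in genetic (cM) coordinates and mapped to bp
#' by inverting the chromosome's Marey curve, so recombination suppression
#' (e.g. pericentromeric plateaus) emerges from the curve itself. For the X in
#' an F1 male, which carries a single X and transmits it without crossing
#' over, the first input haplotype is returned intact.
#'
#' @param chrom A `chrom_model`.
#' @param h1,h2 Parental `hap_mosaic` objects tiling the chromosome.
#' @param is_f1_male_x Logical; if `TRUE`, return `h1` verbatim.
#' @return A `hap_mosaic` for the transmitted gamete.
#' @export
simulate_meiosis <- function(chrom, h1, h2, is_f1_male_x = FALSE) {
  if (any(diff(chrom$marey_cm) < 0)) stop("non-monotone Marey curve")
  if (is_f1_male_x) return(h1)
  M <- chrom_map_length(chrom)
  n_xo <- stats::rpois(1, M / 100)
  start_with_h1 <- stats::runif(1) < 0.5
  if (n_xo == 0) return(if (start_with_h1) h1 else h2)
  brk <- sort(marey_cm_to_bp(chrom, stats::runif(n_xo, 0, M)))
  brk <- brk[brk > 0 & brk < chrom$length_bp]
  if (length(brk) == 0) return(if (start_with_h1) h1 else h2)
  bounds <- sort(unique(c(0, brk, h1$end, h2$end)))
  mid <- (bounds[-1] + bounds[-length(bounds)]) / 2
  from_h1 <- (findInterval(mid, brk) %% 2 == 0) == start_with_h1
  origin <- ifelse(from_h1, mosaic_origin_at(h1, mid), mosaic_origin_at(h2, mid))
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1],
                     origin = origin, stringsAsFactors = FALSE)
  mosaic_simplify(segs)
}

# --- simulation configuration ----------------------------------------------

#' X-linked QTL model for generation time
#'
#' Class means follow the cross design: males are hemizygous (AZ or UT
#' maternal gamete), females are AZ/UT heterozygous or UT/UT. Defaults are the
#' population generation-time means of the motivating beetle cross (AZ 149 d,
#' UT 76 d) with partial dominance of the short (UT) haplotype in
#' heterozygous females.
#'
#' @param chrom Chromosome carrying the QTL.
#' @param pos_bp QTL physical position (true coordinates).
#' @param mean_az_hemi,mean_ut_hemi Male hemizygote means (days).
#' @param mean_het_female,mean_ut_female Female class means (days).
#' @param resid_sd Residual standard deviation (days).
#' @return A list of class `qtl_model`.
#' @export
qtl_model <- function(chrom = "X", pos_bp = 58e6, mean_az_hemi = 149,
                      mean_ut_hemi = 76, mean_het_female = 95,
                      mean_ut_female = 76, resid_sd = 10) {
  lo <- min(mean_ut_female, mean_az_hemi); hi <- max(mean_ut_female, mean_az_hemi)
  if (mean_het_female < lo || mean_het_female > hi)
    stop("mean_het_female must lie between the UT female and AZ means")
  structure(list(chrom = chrom, pos_bp = pos_bp, mean_az_hemi = mean_az_hemi,
                 mean_ut_hemi = mean_ut_hemi,
                 mean_het_female = mean_het_female,
                 mean_ut_female = mean_ut_female, resid_sd = resid_sd),
            class = "qtl_model")
}

#' Observation model for genotype calls
#'
#' Per-call corruption applied to true genotypes: random genotyping error,
#' missingness, and — for male X calls inside the neo-X/neo-Y "similar"
#' region — contamination by neo-Y reads that makes hemizygous calls appear
#' heterozygous.
#'
#' @param genotype_error_rate,missing_rate,neoy_contamination_rate
#'   Probabilities per call, each in `[0, 1]`.
#' @param depth_mean,gq_mean Means of the simulated DP and GQ fields.
#' @return A list of class `obs_model`.
#' @export
obs_model <- function(genotype_error_rate = 0.001, missing_rate = 0.05,
                      neoy_contamination_rate = 0.01, depth_mean = 60,
                      gq_mean = 90) {
  rates <- c(genotype_error_rate, missing_rate, neoy_contamination_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  structure(list(genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 neoy_contamination_rate = neoy_contamination_rate,
                 depth_mean = depth_mean, gq_mean = gq_mean),
            class = "obs_model")
}

#' Viability selection against recombinant male X gametes
#'
#' Males whose maternal X gamete carries a crossover inside `region` survive
#' with probability `male_recombinant_survival`; non-survivors are replaced by
#' rejection sampling. The default region is the 26.9-49.0 Mb interval in
#' which no surviving F2 male of the motivating cross carried a crossover.
#'
#' @param region `c(start_bp, end_bp)` on the X.
#' @param male_recombinant_survival Survival probability in `[0, 1]`.
#' @return A list of class `viability_model`.
#' @export
viability_model <- function(region = c(26.9e6, 49.0e6),
                            male_recombinant_survival = 0) {
  if (male_recombinant_survival < 0 || male_recombinant_survival > 1)
    stop("male_recombinant_survival must be in [0, 1]")
  structure(list(region = region,
                 male_recombinant_survival = male_recombinant_survival),
            class = "viability_model")
}

# --- the cross --------------------------------------------------------------

# breakpoints of a mosaic falling inside [a, b]
breakpoints_in <- function(mosaic, a, b) {
  brk <- mosaic$end[-nrow(mosaic)]
  sum(brk >= a & brk <= b)
}

#' Simulate a neo-sex-chromosome F2 intercross
#'
#' Simulates the P0 (UT female x AZ male) -> F1 intercross -> F2 design.
#' F1 females are AZ/UT at every chromosome; the F1 male carries a single
#' maternally inherited UT X that he transmits to daughters without crossing
#' over, and a neo-Y (no second X) to sons. Every F2 therefore carries exactly
#' one maternally recombined X: females are AZ/UT or UT/UT, males hemizygous.
#' Phenotypes are generation time (X-linked QTL model) and body size
#' (20 autosomal loci of equal small effect plus noise, a "no detectable QTL"
#' polygenic regime). The full gamete truth is recorded.
#'
#' @param genome List of `chrom_model`s (see [default_genome()]).
#' @param markers Marker table (`chrom`, `pos` in reference bp), e.g. from
#'   [place_markers()]; defaults to ~822 markers.
#' @param n_f2 Number of F2 individuals (>= 2).
#' @param qtl A [qtl_model()].
#' @param obs An [obs_model()]; corruption is applied by
#'   [apply_observation_model()]. Use `NULL` to return noise-free calls.
#' @param viability Optional [viability_model()].
#' @param seed Integer seed for the dataset's single RNG stream.
#' @param body_loci Number of autosomal body-size loci.
#' @return A list of class `sim_dataset`: `genotypes` (a [geno_matrix()]),
#'   `phenotypes` (data.frame: `id`, `sex`, `generation_time`, `body_size`),
#'   and `truth` (gamete mosaics, true genotype codes, QTL model, inversions,
#'   seed).
#' @export
simulate_cross <- function(genome = default_genome(), markers = NULL,
                           n_f2 = 181, qtl = qtl_model(), obs = obs_model(),
                           viability = NULL, seed = 1, body_loci = 20) {
  if (n_f2 < 2) stop("n_f2 must be >= 2")
  set.seed(seed)
  if (is.null(markers)) markers <- place_markers(genome)
  bad <- vapply(seq_len(nrow(markers)), function(i) {
    g <- genome[[markers$chrom[i]]]
    is.null(g) || markers$pos[i] < 1 || markers$pos[i] > g$length_bp
  }, logical(1))
  if (any(bad))
    stop("marker outside chromosome: ",
         paste0(markers$chrom[bad], ":", markers$pos[bad], collapse = ", "))
  chrom_names <- names(genome)
  x_name <- chrom_names[vapply(genome, function(g) g$is_x, logical(1))]

  # true physical positions (inversions reflected) for genotype extraction
  markers$true_pos <- markers$pos
  for (nm in chrom_names) {
    sel <- markers$chrom == nm
    markers$true_pos[sel] <- true_marker_pos(genome[[nm]], markers$pos[sel])
  }

  # F1 parents of the intercross
  f1_dam <- lapply(genome, function(g)
    list(pure_mosaic(g$length_bp, "AZ"), pure_mosaic(g$length_bp, "UT")))
  f1_sire_auto <- lapply(genome, function(g)
    list(pure_mosaic(g$length_bp, "AZ"), pure_mosaic(g$length_bp, "UT")))
  x_model <- genome[[x_name]]
  f1_sire_x <- pure_mosaic(x_model$length_bp, "UT")

  draw_f2 <- function() {
    sex <- if (stats::runif(1) < 0.5) "M" else "F"
    mat <- pat <- vector("list", length(genome))
    names(mat) <- names(pat) <- chrom_names
    for (nm in chrom_names) {
      g <- genome[[nm]]
      if (g$is_x) {
        mat[[nm]] <- simulate_meiosis(g, f1_dam[[nm]][[1]], f1_dam[[nm]][[2]])
        pat[[nm]] <- if (sex == "F")
          simulate_meiosis(g, f1_sire_x, f1_sire_x, is_f1_male_x = TRUE)
        else NULL  # neo-Y placeholder: males carry no second X
      } else {
        mat[[nm]] <- simulate_meiosis(g, f1_dam[[nm]][[1]], f1_dam[[nm]][[2]])
        pat[[nm]] <- simulate_meiosis(g, f1_sire_auto[[nm]][[1]],
                                      f1_sire_auto[[nm]][[2]])
      }
    }
    list(sex = sex, maternal = mat, paternal = pat)
  }

  f2 <- vector("list", n_f2)
  for (i in seq_len(n_f2)) {
    repeat {
      ind <- draw_f2()
      if (is.null(viability) || ind$sex == "F") break
      n_rec <- breakpoints_in(ind$maternal[[x_name]], viability$region[1],
                              viability$region[2])
      if (n_rec == 0 || stats::runif(1) < viability$male_recombinant_survival)
        break
    }
    f2[[i]] <- ind
  }
  sexes <- vapply(f2, `[[`, character(1), "sex")
  ids <- sprintf("F2_%03d", seq_len(n_f2))

  # true genotype codes: AZ-allele dosage (male X: hemizygous origin as 2/0)
  n_mark <- nrow(markers)
  truth_geno <- matrix(NA_integer_, n_mark, n_f2 + 2,
                       dimnames = list(NULL, c("P0_dam", "P0_sire", ids)))
  is_x_marker <- markers$chrom == x_name
  truth_geno[, "P0_dam"] <- 0L                      # UT/UT everywhere
  truth_geno[, "P0_sire"] <- 2L                     # AZ/AZ, X hemizygous AZ
  for (i in seq_len(n_f2)) {
    dos <- integer(n_mark)
    for (nm in chrom_names) {
      sel <- which(markers$chrom == nm)
      pos <- markers$true_pos[sel]
      m_az <- mosaic_origin_at(f2[[i]]$maternal[[nm]], pos) == "AZ"
      if (genome[[nm]]$is_x) {
        if (sexes[i] == "M") dos[sel] <- ifelse(m_az, 2L, 0L)
        else dos[sel] <- as.integer(m_az)           # paternal X always UT
      } else {
        p_az <- mosaic_origin_at(f2[[i]]$paternal[[nm]], pos) == "AZ"
        dos[sel] <- as.integer(m_az) + as.integer(p_az)
      }
    }
    truth_geno[, ids[i]] <- dos
  }

  # phenotypes
  qtl_origin <- vapply(f2, function(ind)
    mosaic_origin_at(ind$maternal[[qtl$chrom]], qtl$pos_bp), character(1))
  gen_mean <- ifelse(sexes == "M",
                     ifelse(qtl_origin == "AZ", qtl$mean_az_hemi,
                            qtl$mean_ut_hemi),
                     ifelse(qtl_origin == "AZ", qtl$mean_het_female,
                            qtl$mean_ut_female))
  generation_time <- gen_mean + stats::rnorm(n_f2, 0, qtl$resid_sd)
  auto_names <- setdiff(chrom_names, x_name)
  body_base <- ifelse(sexes == "M", 1.81, 2.05)
  if (length(auto_names) > 0 && body_loci > 0) {
    body_pos <- data.frame(
      chrom = sample(auto_names, body_loci, replace = TRUE),
      stringsAsFactors = FALSE)
    body_pos$pos <- vapply(body_pos$chrom, function(nm)
      stats::runif(1, 1, genome[[nm]]$length_bp), numeric(1))
    a_eff <- 0.09 / (2 * body_loci)  # AZ pronotum wider by ~0.09 mm overall
    body_gen <- vapply(seq_len(n_f2), function(i) {
      d <- 0
      for (j in seq_len(body_loci)) {
        nm <- body_pos$chrom[j]
        d <- d + (mosaic_origin_at(f2[[i]]$maternal[[nm]], body_pos$pos[j]) == "AZ") +
          (mosaic_origin_at(f2[[i]]$paternal[[nm]], body_pos$pos[j]) == "AZ")
      }
      d * a_eff
    }, numeric(1))
  } else body_gen <- numeric(n_f2)
  body_size <- body_base + body_gen + stats::rnorm(n_f2, 0, 0.05)

  phen <- data.frame(id = ids, sex = sexes,
                     generation_time = generation_time,
                     body_size = body_size, stringsAsFactors = FALSE)

  ind <- data.frame(id = c("P0_dam", "P0_sire", ids),
                    sex = c("F", "M", sexes),
                    generation = c("P0", "P0", rep("F2", n_f2)),
                    stringsAsFactors = FALSE)

  # allele bookkeeping for VCF round trips: which allele (ref/alt) is AZ
  origin_az_is_alt <- stats::runif(n_mark) < 0.5
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_mark, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))

  mark_df <- data.frame(chrom = markers$chrom, pos = markers$pos,
                        ref = ref, alt = alt,
                        origin_az_is_alt = origin_az_is_alt,
                        stringsAsFactors = FALSE)
  truth <- list(maternal = lapply(f2, `[[`, "maternal"),
                paternal = lapply(f2, `[[`, "paternal"),
                genotypes = truth_geno, markers = markers,
                qtl = qtl, qtl_origin = qtl_origin,
                inversions = lapply(genome, `[[`, "inversion"),
                x_chrom = x_name, seed = seed)

  calls <- truth_geno
  gm <- geno_matrix(mark_df, ind, calls, polarized = TRUE,
                    x_chrom = x_name)
  if (!is.null(obs)) gm <- apply_observation_model(gm, obs, genome = genome)

  structure(list(genotypes = gm, phenotypes = phen, truth = truth),
            class = "sim_dataset")
}

#' Apply the observation model to true genotype calls
#'
#' Independently per call: with `missing_rate` the call is set `NA`; with
#' `genotype_error_rate` it is replaced by a uniformly chosen different code;
#' male X calls inside the X's "similar" region additionally become
#' heterozygous with `neoy_contamination_rate` (the neo-Y-read artifact).
#' Hemizygous male X truth enters already emitted as the homozygous-appearing
#' code of its single origin. DP and GQ fields are drawn from Poisson
#' distributions with the model's means.
#'
#' @param gm A polarized [geno_matrix()] of true calls.
#' @param model An [obs_model()].
#' @param genome Genome list supplying the X's `similar_region`.
#' @return A `geno_matrix` with corrupted calls and DP/GQ fields.
#' @export
apply_observation_model <- function(gm, model, genome = default_genome()) {
  calls <- gm$calls
  n <- length(calls)
  x_name <- gm$x_chrom
  sim_reg <- if (!is.null(genome[[x_name]])) genome[[x_name]]$similar_region
  if (!is.null(sim_reg) && model$neoy_contamination_rate > 0) {
    male_cols <- which(gm$ind$sex == "M" & gm$ind$generation != "P0")
    x_rows <- which(gm$markers$chrom == x_name &
                      gm$markers$pos >= sim_reg[1] &
                      gm$markers$pos <= sim_reg[2])
    if (length(male_cols) && length(x_rows)) {
      sub <- calls[x_rows, male_cols, drop = FALSE]
      hit <- matrix(stats::runif(length(sub)) < model$neoy_contamination_rate,
                    nrow(sub))
      sub[hit & !is.na(sub)] <- 1L
      calls[x_rows, male_cols] <- sub
    }
  }
  if (model$genotype_error_rate > 0) {
    err <- which(stats::runif(n) < model$genotype_error_rate & !is.na(calls))
    if (length(err)) {
      shift <- sample(1:2, length(err), replace = TRUE)
      calls[err] <- (calls[err] + shift) %% 3L
    }
  }
  if (model$missing_rate > 0)
    calls[stats::runif(n) < model$missing_rate] <- NA_integer_
  dp <- matrix(stats::rpois(n, model$depth_mean), nrow(calls),
               dimnames = dimnames(calls))
  gq <- matrix(pmin(99L, stats::rpois(n, model$gq_mean)), nrow(calls),
               dimnames = dimnames(calls))
  gm$calls <- calls
  gm$dp <- dp
  gm$gq <- gq
  gm
}

#' Simulate per-window sequencing depth for one male and one female
#'
#' Emulates whole-genome coverage of a male and a female mapped to a female
#' reference: autosomes at full depth in both sexes; on the X the male is at
#' full depth over the neo-X/neo-Y "similar" region, intermediate over the
#' interior, and half depth over the hemizygous ancestral-X.
#'
#' @param genome Genome list.
#' @param window_bp Window size.
#' @param depth Female (and autosomal) mean depth.
#' @param breaks `c(a, b)`: X positions where male relative depth steps from
#'   1.0 to 0.75 and from 0.75 to 0.5.
#' @param noise_sd Multiplicative noise standard deviation.
#' @return A data.frame: `sample`, `chrom`, `start` (0-based), `depth`.
#' @export
simulate_depth <- function(genome = default_genome(), window_bp = 50000,
                           depth = 30, breaks = c(26e6, 48e6),
                           noise_sd = 0.03) {
  out <- list()
  for (nm in names(genome)) {
    g <- genome[[nm]]
    starts <- seq(0, g$length_bp - 1, by = window_bp)
    for (smp in c("female", "male")) {
      rel <- rep(1, length(starts))
      if (g$is_x && smp == "male") {
        mids <- starts + window_bp / 2
        rel <- ifelse(mids < breaks[1], 1,
                      ifelse(mids < breaks[2], 0.75, 0.5))
      }
      d <- depth * rel * pmax(0, 1 + stats::rnorm(length(starts), 0, noise_sd))
      out[[length(out) + 1]] <- data.frame(sample = smp, chrom = nm,
                                           start = starts, depth = d,
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
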