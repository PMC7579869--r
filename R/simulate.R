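# Synthetic founder-haplotype panels. The generative model mirrors what the
# analysis assumes: one founder chromosome carries the mutation; each sampled
# carrier chromosome descends from it through g meioses, so the retained
# founder segment around the focal position has one-sided genetic extents
# Exponential(rate = g) in Morgans (a star genealogy), truncated at the
# region edges. Everything outside the retained segment — and every control
# chromosome — is drawn from an LD-free background model.

#' Simulation configuration
#'
#' Defaults emulate the study conditions at desk scale: a Colombia-like
#' carrier series (founding ~26 generations ago under strong growth) typed on
#' an array with one marker per ~5 kb across a 20-Mb window around the BRCA1
#' locus, MAF above 0.05, light genotyping error and missingness.
#'
#' @param n_markers number of markers (default: one per ~5 kb of the region).
#' @param region_bp `c(start, end)` of the simulated window (GRCh37 chr17
#'   coordinates by default).
#' @param chrom chromosome name.
#' @param maf_range `c(low, high)` minor-allele-frequency range for
#'   background frequencies, `0 < low <= high <= 0.5`.
#' @param recomb_rate_cM_per_Mb constant recombination rate (default 1).
#' @param g_true generations since founding (default 26, Colombia-like).
#' @param d per-generation growth rate of the carrier lineage count (default
#'   0.42); only used when `growth_depths = TRUE`.
#' @param growth_depths draw lineage depths from the growing-population
#'   approximation (`depth = g - T`, `T ~ Exponential(d)` truncated to
#'   `[0, g]`) instead of fixing them at `g_true`.
#' @param n_carriers,n_controls diploid sample counts (defaults 32 carriers,
#'   150 controls).
#' @param n_lineages 1 (default) or 2 founder lineages; with 2, the second
#'   founder shares the first founder's alleles inside `shared_core_bp` around
#'   the focal position and carries an independent background elsewhere (an
#'   early recombination event onto another chromosome).
#' @param lineage_prop fraction of carriers in lineage 1 when `n_lineages = 2`.
#' @param shared_core_bp half-width structure `c(start, end)` of the region
#'   both founders share (default the ~264-kb window around the focal
#'   position).
#' @param focal a [focal_mutation()]; must lie inside `region_bp`.
#' @param genotyping_error_rate per-allele flip probability (default 0.002).
#' @param missing_rate per-allele missing probability (default 0.01).
#' @param seed RNG seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_markers = NULL,
                       region_bp = c(31244000L, 51244000L),
                       chrom = "17",
                       maf_range = c(0.05, 0.5),
                       recomb_rate_cM_per_Mb = 1.0,
                       g_true = 26L, d = 0.42, growth_depths = FALSE,
                       n_carriers = 32L, n_controls = 150L,
                       n_lineages = 1L, lineage_prop = 0.5,
                       shared_core_bp = NULL,
                       focal = focal_mutation(chrom = chrom),
                       genotyping_error_rate = 0.002,
                       missing_rate = 0.01, seed = 1L) {
  if (is.null(n_markers)) {
    n_markers <- max(2L, as.integer(round((region_bp[2L] - region_bp[1L]) / 5000)))
  }
  if (maf_range[1L] <= 0 || maf_range[1L] > maf_range[2L] ||
      maf_range[2L] > 0.5) {
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  }
  if (g_true < 0) stop("g_true must be >= 0")
  rates <- c(genotyping_error_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (focal$pos_bp <= region_bp[1L] || focal$pos_bp >= region_bp[2L]) {
    stop("focal position must lie inside region_bp")
  }
  if (!n_lineages %in% 1:2) stop("n_lineages must be 1 or 2")
  if (is.null(shared_core_bp)) {
    shared_core_bp <- c(focal$pos_bp - 132000L, focal$pos_bp + 132000L)
  }
  structure(list(n_markers = as.integer(n_markers), region_bp = region_bp,
                 chrom = chrom, maf_range = maf_range,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 g_true = g_true, d = d, growth_depths = growth_depths,
                 n_carriers = as.integer(n_carriers),
                 n_controls = as.integer(n_controls),
                 n_lineages = as.integer(n_lineages),
                 lineage_prop = lineage_prop,
                 shared_core_bp = shared_core_bp, focal = focal,
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw one background haplotype
#'
#' Independent Bernoulli draws per marker (an LD-free null for non-carrier
#' chromosomes).
#'
#' @param freqs per-marker alt-allele frequencies in (0, 1) (frequency 1 or 0
#'   allowed as a degenerate case).
#' @return Integer 0/1 haplotype.
#' @export
simulate_background_haplotype <- function(freqs) {
  if (any(freqs < 0 | freqs > 1)) stop("freqs must be in [0, 1]")
  as.integer(stats::runif(length(freqs)) < freqs)
}

# matrix of n background haplotypes
background_matrix <- function(n, freqs) {
  m <- matrix(stats::runif(n * length(freqs)), nrow = n)
  out <- matrix(as.integer(m < rep(freqs, each = n)), nrow = n)
  out
}

#' Simulate a carrier/control haplotype panel with truth record
#'
#' See the package-level description of the generative model. The truth
#' record retains everything downstream stages are tested against: the
#' founder haplotype(s), each carrier chromosome's retained interval (in cM
#' and as marker indices, pre-error), lineage assignments, `g_true` and the
#' seed.
#'
#' @param config a [sim_config()].
#' @return A list with `panel` (a [haplotype_panel()]) and `truth`.
#' @export
simulate_carrier_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rb <- config$region_bp
  pos <- sort(sample.int(rb[2L] - rb[1L] - 1L, config$n_markers)) + rb[1L]
  cm <- (pos - rb[1L]) * config$recomb_rate_cM_per_Mb / 1e6
  map <- marker_map(id = sprintf("mk%06d", seq_along(pos)),
                    chrom = config$chrom, pos_bp = pos, pos_cM = cm,
                    chrom_length_bp = max(CHR17_LENGTH_BP, rb[2L]))
  maf <- stats::runif(config$n_markers, config$maf_range[1L],
                      config$maf_range[2L])
  flip <- stats::runif(config$n_markers) < 0.5
  freqs <- ifelse(flip, maf, 1 - maf)
  focal_cM <- marker_cM_at(map, config$focal$pos_bp)
  region_cM_left <- focal_cM - 0       # region start is cM origin
  region_cM_right <- cm[length(cm)] - focal_cM
  founders <- list(simulate_background_haplotype(freqs))
  if (config$n_lineages == 2L) {
    f2 <- simulate_background_haplotype(freqs)
    core_idx <- which(pos >= config$shared_core_bp[1L] &
                        pos <= config$shared_core_bp[2L])
    f2[core_idx] <- founders[[1L]][core_idx]
    founders[[2L]] <- f2
  }
  n_car <- config$n_carriers
  lineage <- rep(1L, n_car)
  if (config$n_lineages == 2L) {
    n1 <- round(config$lineage_prop * n_car)
    lineage <- c(rep(1L, n1), rep(2L, n_car - n1))
  }
  depths <- rep(config$g_true, n_car)
  if (config$growth_depths && config$g_true > 0) {
    t_trunc <- stats::qexp(stats::runif(n_car) *
                             stats::pexp(config$g_true, rate = config$d),
                           rate = config$d)
    depths <- config$g_true - t_trunc
  }
  draw_extent <- function(depth, edge_cM) {
    if (depth == 0) return(c(edge_cM, TRUE))
    x <- stats::rexp(1L, rate = depth) * 100  # Morgans -> cM
    if (x >= edge_cM) c(edge_cM, TRUE) else c(x, FALSE)
  }
  n_hap <- 2L * (n_car + config$n_controls)
  alleles <- background_matrix(n_hap, freqs)
  left_cM <- numeric(n_car); right_cM <- numeric(n_car)
  left_cens <- logical(n_car); right_cens <- logical(n_car)
  retained <- vector("list", n_car)
  for (i in seq_len(n_car)) {
    L <- draw_extent(depths[i], focal_cM - cm[1L])
    R <- draw_extent(depths[i], cm[length(cm)] - focal_cM)
    left_cM[i] <- L[1L]; left_cens[i] <- as.logical(L[2L])
    right_cM[i] <- R[1L]; right_cens[i] <- as.logical(R[2L])
    # tolerance keeps edge markers inside censored intervals despite
    # floating-point rounding of the cM arithmetic
    idx <- which(cm >= focal_cM - L[1L] - 1e-9 & cm <= focal_cM + R[1L] + 1e-9)
    retained[[i]] <- idx
    alleles[2L * i - 1L, idx] <- founders[[lineage[i]]][idx]
  }
  carries <- rep(FALSE, n_hap)
  carries[2L * seq_len(n_car) - 1L] <- TRUE
  clean_alleles <- alleles
  if (config$genotyping_error_rate > 0) {
    flip <- matrix(stats::runif(length(alleles)) < config$genotyping_error_rate,
                   nrow = n_hap)
    alleles[flip] <- 1L - alleles[flip]
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(alleles)) < config$missing_rate,
                   nrow = n_hap)
    alleles[miss] <- NA_integer_
  }
  samples <- c(sprintf("CAR%03d", seq_len(n_car)),
               sprintf("CTL%03d", seq_len(config$n_controls)))
  sample_of_hap <- rep(samples, each = 2L)
  population <- rep(c("carrier", "control"),
                    times = 2L * c(n_car, config$n_controls))
  panel <- haplotype_panel(map, alleles, sample_of_hap, population, carries)
  truth <- list(founder = founders[[1L]], founders = founders,
                lineage = lineage,
                carrier_hap_ids = haplotype_ids(panel)[carries],
                left_extent_cM = left_cM, right_extent_cM = right_cM,
                left_censored = left_cens, right_censored = right_cens,
                retained_marker_idx = retained, depths = depths,
                g_true = config$g_true, seed = config$seed,
                focal = config$focal, clean_alleles = clean_alleles)
  list(panel = panel, truth = truth)
}

#' Simulate Markovian local-ancestry tracks
#'
#' Per-haplotype ancestry labels follow a stationary Markov chain along the
#' genetic map: tract lengths are exponential with mean `tract_scale_cM` and
#' the stationary label distribution equals `proportions`. Between markers
#' separated by `delta` cM the chain keeps its label with probability
#' `exp(-delta/tract_scale_cM)` and otherwise redraws from `proportions`.
#'
#' @param n_hap number of haplotypes.
#' @param map a [marker_map()].
#' @param proportions named per-ancestry stationary proportions summing to 1
#'   (names from `ancestries`).
#' @param tract_scale_cM mean ancestry tract length in cM (default 10,
#'   admixture ~10 generations old).
#' @param sample_of_haplotype,carrier metadata passed to [ancestry_tracks()]
#'   (defaults pair consecutive haplotypes into samples, no carriers).
#' @param ancestries label set.
#' @return An [ancestry_tracks()].
#' @export
simulate_ancestry_tracks <- function(n_hap, map, proportions,
                                     tract_scale_cM = 10,
                                     sample_of_haplotype = NULL,
                                     carrier = FALSE,
                                     ancestries = ANCESTRY_LABELS) {
  if (length(proportions) != length(ancestries)) {
    stop("one proportion per ancestry required")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must be non-negative and sum to 1")
  }
  if (n_hap %% 2L != 0L) stop("n_hap must be even (two haplotypes per sample)")
  n_m <- nrow(map)
  lab_idx <- matrix(0L, n_hap, n_m)
  draw <- function(n) {
    sample.int(length(ancestries), n, replace = TRUE, prob = proportions)
  }
  lab_idx[, 1L] <- draw(n_hap)
  if (n_m > 1L) {
    delta <- diff(map$pos_cM)
    p_keep <- exp(-delta / tract_scale_cM)
    for (j in 2L:n_m) {
      keep <- stats::runif(n_hap) < p_keep[j - 1L]
      lab_idx[, j] <- ifelse(keep, lab_idx[, j - 1L], draw(n_hap))
    }
  }
  labels <- matrix(ancestries[lab_idx], n_hap, n_m)
  if (is.null(sample_of_haplotype)) {
    sample_of_haplotype <- rep(sprintf("S%04d", seq_len(n_hap / 2L)), each = 2L)
  }
  ancestry_tracks(map, labels, sample_of_haplotype, carrier, ancestries)
}

#' Write a simulated dataset to disk
#'
#' Emits the phased VCF, a PLINK-style map, the ancestry tracks (if given)
#' and a truth JSON.
#'
#' @param sim output of [simulate_carrier_panel()].
#' @param dir output directory (created if needed).
#' @param tracks optional [ancestry_tracks()].
#' @return Invisibly, the list of paths written.
#' @export
write_simulation <- function(sim, dir, tracks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "panel.vcf")
  write_phased_vcf(sim$panel, vcf)
  map_path <- file.path(dir, "markers.map")
  m <- sim$panel$map
  utils::write.table(data.frame(m$chrom, m$id, m$pos_cM, m$pos_bp),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  tr <- sim$truth
  tr$retained_marker_idx <- NULL
  tr$clean_alleles <- NULL
  tr$focal <- unclass(tr$focal)
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA)
  paths <- list(vcf = vcf, map = map_path, truth = truth_path)
  if (!is.null(tracks)) {
    paths$ancestry <- file.path(dir, "ancestry.tsv")
    write_ancestry_tracks(tracks, paths$ancestry)
  }
  invisible(paths)
}
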