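#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on biallelic genotype counts using the conditional
#' (Levene/Haldane) distribution of the heterozygote count given the observed
#' allele counts. The p-value is the sum of conditional probabilities of all
#' heterozygote configurations whose probability does not exceed that of the
#' observed configuration.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(5, 0, 5)   # strong heterozygote deficit
#' hwe_exact_test(25, 50, 25)
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0L) {
    warning("all genotype counts are zero; returning p = 1")
    return(1)
  }
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)  # single possible configuration
  # heterozygote count shares the parity of the minor allele count
  h_min <- if (nA %% 2L == 0L) 0L else 1L
  h <- seq.int(h_min, min(nA, na), by = 2L)
  # log P(n_Aa = h | n, nA) up to a common constant:
  #   n! / (nAA! nAa! naa!) * 2^nAa  with nAA = (nA - h)/2, naa = (na - h)/2
  logp <- h * log(2) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, h)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Remove low-call-rate samples
#'
#' @param gt a [genotype_table()].
#' @param min_call_rate minimum fraction of non-missing genotypes a sample
#'   must have to be kept (default 0.95).
#' @return A list with `table` (filtered [genotype_table()]) and `report`
#'   (a `qc_report`, see [qc_report()]). Sample order is preserved.
#' @export
filter_samples <- function(gt, min_call_rate = 0.95) {
  stopifnot(inherits(gt, "genotype_table"))
  if (nrow(gt$genotypes) == 0L) stop("empty genotype table")
  call_rate <- rowMeans(!is.na(gt$genotypes))
  drop <- call_rate < min_call_rate
  report <- qc_report(
    samples_removed = data.frame(
      id = rownames(gt$genotypes)[drop],
      reason = rep("call_rate", sum(drop)),
      statistic = call_rate[drop],
      stringsAsFactors = FALSE, row.names = NULL),
    markers_removed = empty_removals(),
    thresholds = list(min_call_rate = min_call_rate))
  list(table = genotype_table(gt$map,
                              gt$genotypes[!drop, , drop = FALSE]),
       report = report)
}

#' Remove markers failing call-rate, MAF or Hardy-Weinberg thresholds
#'
#' A marker is removed if its call rate is below `min_call_rate`, OR its minor
#' allele frequency (computed on non-missing genotypes) is `<= maf_min`
#' (inclusive), OR its exact Hardy-Weinberg p-value is `<= hwe_p_min`. Rules
#' are evaluated in that order and only the first triggering rule is recorded.
#'
#' @param gt a [genotype_table()].
#' @param min_call_rate minimum marker call rate (default 0.95).
#' @param maf_min inclusive minor-allele-frequency exclusion threshold
#'   (default 0.05).
#' @param hwe_p_min inclusive Hardy-Weinberg exact-p exclusion threshold
#'   (default 1e-5).
#' @return A list with `table` and `report` as in [filter_samples()].
#' @export
filter_markers <- function(gt, min_call_rate = 0.95, maf_min = 0.05,
                           hwe_p_min = 1e-5) {
  stopifnot(inherits(gt, "genotype_table"))
  g <- gt$genotypes
  if (ncol(g) == 0L) stop("empty genotype table")
  n_obs <- colSums(!is.na(g))
  call_rate <- n_obs / nrow(g)
  alt_freq <- colSums(g, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  maf <- pmin(alt_freq, 1 - alt_freq)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    hwe_exact_test(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                   sum(x == 2L, na.rm = TRUE))
  }, numeric(1L))
  reason <- rep(NA_character_, ncol(g))
  statistic <- rep(NA_real_, ncol(g))
  fail_cr <- call_rate < min_call_rate
  fail_maf <- !fail_cr & maf <= maf_min
  fail_hwe <- !fail_cr & !fail_maf & hwe_p <= hwe_p_min
  reason[fail_cr] <- "call_rate"; statistic[fail_cr] <- call_rate[fail_cr]
  reason[fail_maf] <- "maf"; statistic[fail_maf] <- maf[fail_maf]
  reason[fail_hwe] <- "hwe"; statistic[fail_hwe] <- hwe_p[fail_hwe]
  drop <- !is.na(reason)
  keep_map <- gt$map[!drop, , drop = FALSE]
  attr(keep_map, "chrom_length_bp") <- attr(gt$map, "chrom_length_bp")
  attr(keep_map, "chrom_length_cM") <- attr(gt$map, "chrom_length_cM")
  class(keep_map) <- class(gt$map)
  report <- qc_report(
    samples_removed = data.frame(id = character(), reason = character(),
                                 statistic = numeric(), stringsAsFactors = FALSE),
    markers_removed = data.frame(
      id = gt$map$id[drop], reason = reason[drop], statistic = statistic[drop],
      stringsAsFactors = FALSE, row.names = NULL),
    thresholds = list(min_call_rate = min_call_rate, maf_min = maf_min,
                      hwe_p_min = hwe_p_min))
  list(table = genotype_table(keep_map, g[, !drop, drop = FALSE]),
       report = report)
}

empty_removals <- function() {
  data.frame(id = character(), reason = character(), statistic = numeric(),
             stringsAsFactors = FALSE)
}

#' Assemble a QC report
#'
#' @param samples_removed,markers_removed data frames with columns `id`,
#'   `reason`, `statistic` (one triggering rule and its statistic per removal).
#' @param thresholds named list of thresholds applied.
#' @return A list of class `"qc_report"`.
#' @export
qc_report <- function(samples_removed, markers_removed, thresholds) {
  stopifnot(all(c("id", "reason", "statistic") %in% names(samples_removed)),
            all(c("id", "reason", "statistic") %in% names(markers_removed)))
  structure(list(samples_removed = samples_removed,
                 markers_removed = markers_removed,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d sample(s), %d marker(s) removed\n",
              nrow(x$samples_removed), nrow(x$markers_removed)))
  thr <- paste(names(x$thresholds), unlist(x$thresholds), sep = "=",
               collapse = ", ")
  cat("Thresholds:", thr, "\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  rows <- rbind(
    if (nrow(report$samples_removed)) cbind(kind = "sample", report$samples_removed),
    if (nrow(report$markers_removed)) cbind(kind = "marker", report$markers_removed))
  if (is.null(rows)) {
    rows <- data.frame(kind = character(), id = character(),
                       reason = character(), statistic = numeric())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply marker QC to a phased panel
#'
#' Runs [filter_samples()] then [filter_markers()] on the panel's collapsed
#' genotypes and restricts the panel to surviving samples and markers.
#'
#' @param panel a [haplotype_panel()].
#' @inheritParams filter_markers
#' @inheritParams filter_samples
#' @return A list with `panel` (filtered) and `report` (merged `qc_report`).
#' @export
qc_panel <- function(panel, min_call_rate = 0.95, maf_min = 0.05,
                     hwe_p_min = 1e-5) {
  gt <- panel_to_genotypes(panel)
  s <- filter_samples(gt, min_call_rate = min_call_rate)
  m <- filter_markers(s$table, min_call_rate = min_call_rate,
                      maf_min = maf_min, hwe_p_min = hwe_p_min)
  keep_samples <- rownames(s$table$genotypes)
  keep_hap <- panel$sample_of_haplotype %in% keep_samples
  keep_marker <- panel$map$id %in% m$table$map$id
  out <- haplotype_panel(m$table$map,
                         panel$alleles[keep_hap, keep_marker, drop = FALSE],
                         panel$sample_of_haplotype[keep_hap],
                         panel$population[keep_hap],
                         panel$carries_mutation[keep_hap])
  report <- qc_report(s$report$samples_removed, m$report$markers_removed,
                      m$report$thresholds)
  list(panel = out, report = report)
}
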