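#' Ancestry labels recognised by default
#' @export
ANCESTRY_LABELS <- c("EUR", "AMR", "AFR")

#' Construct a set of per-marker local-ancestry tracks
#'
#' @param map a [marker_map()].
#' @param labels character matrix `[n_haplotypes x n_markers]` of ancestry
#'   labels.
#' @param sample_of_haplotype sample id per haplotype row (each sample twice).
#' @param carrier logical per haplotype: does the sample carry the focal
#'   mutation?
#' @param ancestries allowed label set (default [ANCESTRY_LABELS]).
#' @return A list of class `"ancestry_tracks"`.
#' @export
ancestry_tracks <- function(map, labels, sample_of_haplotype, carrier,
                            ancestries = ANCESTRY_LABELS) {
  stopifnot(inherits(map, "marker_map"))
  labels <- as.matrix(labels)
  if (ncol(labels) != nrow(map)) stop("label columns must match map markers")
  if (!all(labels %in% ancestries)) {
    stop("labels outside the ancestry set: ",
         paste(setdiff(unique(as.vector(labels)), ancestries), collapse = ", "))
  }
  n_hap <- nrow(labels)
  sample_of_haplotype <- as.character(sample_of_haplotype)
  if (length(sample_of_haplotype) != n_hap) stop("sample ids must match rows")
  carrier <- rep_len(as.logical(carrier), n_hap)
  if (is.null(rownames(labels))) {
    idx <- stats::ave(seq_len(n_hap), sample_of_haplotype, FUN = seq_along)
    rownames(labels) <- paste0(sample_of_haplotype, "_h", idx)
  }
  structure(list(map = map, labels = labels,
                 sample_of_haplotype = sample_of_haplotype,
                 carrier = carrier, ancestries = ancestries),
            class = "ancestry_tracks")
}

#' @export
print.ancestry_tracks <- function(x, ...) {
  cat(sprintf("Ancestry tracks: %d haplotypes x %d markers; labels {%s}; %d carrier haplotypes\n",
              nrow(x$labels), ncol(x$labels),
              paste(x$ancestries, collapse = ", "), sum(x$carrier)))
  invisible(x)
}

# midpoint-interval weights in bp for each marker: marker i owns
# [mid(i-1, i), mid(i, i+1)], the first interval starting at the chromosome
# start and the last ending at chrom_length_bp, so weights sum exactly to the
# chromosome length.
midpoint_weights <- function(map) {
  pos <- as.numeric(map$pos_bp)
  L <- as.numeric(attr(map, "chrom_length_bp"))
  n <- length(pos)
  if (n == 1L) return(L)
  mids <- (pos[-n] + pos[-1L]) / 2
  bounds <- c(0, mids, L)
  diff(bounds)
}

#' Chromosome-level ancestry fractions of one haplotype
#'
#' Each marker is assigned the interval between the midpoints to its
#' neighbouring markers (first and last intervals extend to the chromosome
#' ends); the fraction of each ancestry is the summed interval length carrying
#' that label divided by the total chromosome length.
#'
#' @param track character vector of per-marker ancestry labels for one
#'   haplotype.
#' @param map a [marker_map()] (its `chrom_length_bp` attribute is the
#'   denominator).
#' @param ancestries label set (default [ANCESTRY_LABELS]).
#' @return Named numeric vector of fractions summing to 1.
#' @export
chromosome_ancestry_fraction <- function(track, map,
                                         ancestries = ANCESTRY_LABELS) {
  if (length(track) != nrow(map)) stop("track length must match map markers")
  if (length(track) < 2L) {
    warning("single marker; whole chromosome assigned to its label")
  }
  w <- midpoint_weights(map)
  total <- sum(w)
  vapply(ancestries, function(a) sum(w[track == a]) / total, numeric(1L))
}

#' Per-marker ancestry fractions over a haplotype subset
#'
#' @param tracks an [ancestry_tracks()].
#' @param subset logical/integer/character selector of haplotype rows
#'   (default: carrier haplotypes).
#' @return Matrix `[ancestries x markers]` of fractions; columns sum to 1.
#' @export
per_marker_fraction <- function(tracks, subset = NULL) {
  if (is.null(subset)) subset <- tracks$carrier
  lab <- tracks$labels[subset, , drop = FALSE]
  if (nrow(lab) == 0L) stop("empty haplotype subset")
  out <- matrix(0, length(tracks$ancestries), ncol(lab),
                dimnames = list(tracks$ancestries, tracks$map$id))
  for (a in tracks$ancestries) out[a, ] <- colMeans(lab == a)
  out
}

#' Two-sample t test
#'
#' Pooled-variance Student's t test by default (`equal_variance = TRUE`) with
#' a Welch option, via [stats::t.test()]. Degenerate zero-variance inputs are
#' resolved before delegation: equal means give `t = 0, p = 1`; unequal means
#' with zero variance give the `p -> 0` limit with a warning.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param equal_variance pooled Student's t (default) or Welch.
#' @return A list with `t`, `df`, `p`.
#' @export
two_sample_t_test <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    df <- if (equal_variance) length(x) + length(y) - 2 else NA_real_
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
    warning("zero variance with unequal means; p = 0 limit")
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = equal_variance)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Compare chromosome ancestry between carriers and non-carriers
#'
#' Computes per-sample chromosome ancestry fractions (mean of the sample's two
#' haplotypes) for one ancestry and tests carriers against non-carriers with
#' Student's t test. Values are reported as mean +/- SD per group.
#'
#' @param tracks an [ancestry_tracks()].
#' @param ancestry which ancestry fraction to compare (default `"EUR"`).
#' @param equal_variance pooled Student's t (default) or Welch.
#' @param per_haplotype compare per-haplotype instead of per-sample fractions.
#' @return A list of class `"ancestry_comparison"` with group sizes, means,
#'   SDs, and `t`, `df`, `p`.
#' @export
compare_carrier_ancestry <- function(tracks, ancestry = "EUR",
                                     equal_variance = TRUE,
                                     per_haplotype = FALSE) {
  frac_hap <- vapply(seq_len(nrow(tracks$labels)), function(i) {
    chromosome_ancestry_fraction(tracks$labels[i, ], tracks$map,
                                 tracks$ancestries)[[ancestry]]
  }, numeric(1L))
  if (per_haplotype) {
    values <- frac_hap
    is_carrier <- tracks$carrier
  } else {
    samples <- unique(tracks$sample_of_haplotype)
    values <- vapply(samples, function(s) {
      mean(frac_hap[tracks$sample_of_haplotype == s])
    }, numeric(1L))
    is_carrier <- vapply(samples, function(s) {
      any(tracks$carrier[tracks$sample_of_haplotype == s])
    }, logical(1L))
  }
  carriers <- values[is_carrier]
  controls <- values[!is_carrier]
  if (length(carriers) == 0L || length(controls) == 0L) {
    stop("both carrier and non-carrier groups must be present")
  }
  tt <- two_sample_t_test(carriers, controls, equal_variance = equal_variance)
  structure(list(ancestry = ancestry,
                 n_carrier = length(carriers), n_control = length(controls),
                 carrier_mean = mean(carriers), carrier_sd = stats::sd(carriers),
                 control_mean = mean(controls), control_sd = stats::sd(controls),
                 t = tt$t, df = tt$df, p = tt$p,
                 per_haplotype = per_haplotype),
            class = "ancestry_comparison")
}

#' @export
print.ancestry_comparison <- function(x, ...) {
  cat(sprintf("Chromosome %s ancestry, carriers vs non-carriers (%s)\n",
              x$ancestry, if (x$per_haplotype) "per haplotype" else "per sample"))
  cat(sprintf("  carriers (n=%d): %.4f +/- %.4f\n", x$n_carrier,
              x$carrier_mean, x$carrier_sd))
  cat(sprintf("  controls (n=%d): %.4f +/- %.4f\n", x$n_control,
              x$control_mean, x$control_sd))
  cat(sprintf("  Student's t = %.3f, df = %.1f, P = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Write ancestry tracks as TSV (haplotype_id, marker_id, label)
#' @param tracks an [ancestry_tracks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ancestry_tracks <- function(tracks, path) {
  out <- data.frame(
    haplotype_id = rep(rownames(tracks$labels), each = ncol(tracks$labels)),
    marker_id = rep(tracks$map$id, times = nrow(tracks$labels)),
    label = as.vector(t(tracks$labels)), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ancestry tracks from TSV
#'
#' @param path TSV with columns `haplotype_id`, `marker_id`, `label`.
#' @param map a [marker_map()] ordering the markers.
#' @param sample_of_haplotype,carrier per-haplotype metadata in the order the
#'   haplotypes appear in the file; defaults derive sample ids by stripping a
#'   trailing `_h1`/`_h2` and set `carrier = FALSE`.
#' @param ancestries allowed label set.
#' @return An [ancestry_tracks()].
#' @export
read_ancestry_tracks <- function(path, map, sample_of_haplotype = NULL,
                                 carrier = FALSE,
                                 ancestries = ANCESTRY_LABELS) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  haps <- unique(tab$haplotype_id)
  labels <- matrix(NA_character_, length(haps), nrow(map),
                   dimnames = list(haps, map$id))
  labels[cbind(match(tab$haplotype_id, haps),
               match(tab$marker_id, map$id))] <- tab$label
  if (anyNA(labels)) stop("ancestry TSV does not cover every haplotype/marker")
  if (is.null(sample_of_haplotype)) {
    sample_of_haplotype <- sub("_h[12]$", "", haps)
  }
  ancestry_tracks(map, labels, sample_of_haplotype, carrier, ancestries)
}
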