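# Focal outward-extension detection of conserved haplotypes and pairwise
# shared segments. Extension is anchored at the markers flanking the focal
# mutation (the mutation itself need not be an array marker).

# indices of the nearest markers flanking the focal position; either may be
# NA when the focal position lies beyond the map on that side. A marker at
# exactly the focal position flanks on both sides.
flanking_indices <- function(map, focal) {
  left <- if (any(map$pos_bp <= focal$pos_bp)) max(which(map$pos_bp <= focal$pos_bp)) else NA_integer_
  right <- if (any(map$pos_bp >= focal$pos_bp)) min(which(map$pos_bp >= focal$pos_bp)) else NA_integer_
  c(left = left, right = right)
}

# is a marker column "identical" across haplotypes under a missing policy,
# allowing up to max_mismatch_haps deviations from the column consensus?
column_conserved <- function(a, missing_policy, max_mismatch_haps) {
  if (missing_policy == "mismatch" && anyNA(a)) return(FALSE)
  obs <- a[!is.na(a)]
  if (length(obs) == 0L) return(TRUE)  # no evidence against identity
  n1 <- sum(obs == 1L)
  n0 <- length(obs) - n1
  min(n0, n1) <= max_mismatch_haps
}

# consensus allele of a column: majority over non-missing; ties -> 0
column_consensus <- function(a) {
  obs <- a[!is.na(a)]
  if (length(obs) == 0L) return(NA_integer_)
  if (sum(obs == 1L) > sum(obs == 0L)) 1L else 0L
}

#' Detect the conserved core haplotype around the focal mutation
#'
#' Scans outward from the markers flanking the focal position and extends
#' left and right while all mutation-bearing haplotypes carry an identical
#' allele at the marker (up to `max_mismatch_haps` deviating haplotypes).
#' The boundaries are the last conserved markers on each side; the length is
#' the sum of the one-sided distances from the boundaries, i.e.
#' `span_bp(left, right)` of the conserved region.
#'
#' @param panel a [haplotype_panel()]; only haplotypes with
#'   `carries_mutation = TRUE` are analyzed (all haplotypes if none flagged
#'   and `use_all = TRUE`).
#' @param focal a [focal_mutation()].
#' @param missing_policy how a missing allele enters the identity test:
#'   `"ignore"` (default; the haplotype is skipped at that marker),
#'   `"mismatch"` (missing breaks identity), or `"impute-consensus"`
#'   (missing counted as the column consensus, equivalent to `"ignore"` for
#'   the identity decision).
#' @param max_mismatch_haps number of haplotypes allowed to deviate from the
#'   column consensus at a conserved marker (default 0 = strict identity).
#' @param use_all analyze all haplotypes when no mutation flags are set.
#' @return A list of class `"core_haplotype"` with boundary marker ids,
#'   `start_bp`, `end_bp`, `length_bp`, `length_cM`, `consensus_alleles`
#'   (named by marker id) and `n_haplotypes`.
#' @export
find_core_haplotype <- function(panel, focal,
                                missing_policy = c("ignore", "mismatch",
                                                   "impute-consensus"),
                                max_mismatch_haps = 0L, use_all = FALSE) {
  missing_policy <- match.arg(missing_policy)
  map <- panel$map
  rows <- which(panel$carries_mutation)
  if (length(rows) == 0L) {
    if (!use_all) stop("no mutation-bearing haplotypes in panel")
    rows <- seq_len(nrow(panel$alleles))
  }
  if (length(rows) < 2L) stop("need >= 2 mutation-bearing haplotypes")
  a <- panel$alleles[rows, , drop = FALSE]
  fl <- flanking_indices(map, focal)
  if (is.na(fl["left"]) && is.na(fl["right"])) {
    stop("focal position has no flanking marker on either side")
  }
  one_sided <- is.na(fl["left"]) || is.na(fl["right"])
  if (one_sided) {
    warning("focal position outside the marker map on one side; ",
            "returning a one-sided core")
  }
  conserved <- function(j) column_conserved(a[, j], missing_policy,
                                            max_mismatch_haps)
  iL <- NA_integer_
  if (!is.na(fl["left"])) {
    j <- fl[["left"]]
    while (j >= 1L && conserved(j)) { iL <- j; j <- j - 1L }
  }
  iR <- NA_integer_
  if (!is.na(fl["right"])) {
    j <- fl[["right"]]
    # when left and right flank coincide (marker at the focal position) do not
    # rescan it
    if (!is.na(iL) && j < iL) j <- iL
    while (j <= nrow(map) && conserved(j)) { iR <- j; j <- j + 1L }
  }
  # a side where even the flanking marker is not conserved degenerates to the
  # focal position itself
  start_bp <- if (is.na(iL)) focal$pos_bp else map$pos_bp[iL]
  end_bp <- if (is.na(iR)) focal$pos_bp else map$pos_bp[iR]
  if (is.na(iL) && is.na(iR)) {
    warning("no conserved marker flanking the focal position; empty core")
    core_idx <- integer()
  } else {
    lo <- if (is.na(iL)) iR else iL
    hi <- if (is.na(iR)) iL else iR
    core_idx <- seq.int(lo, hi)
  }
  consensus <- vapply(core_idx, function(j) column_consensus(a[, j]),
                      integer(1L))
  names(consensus) <- map$id[core_idx]
  structure(list(
    left_marker_id = if (is.na(iL)) NA_character_ else map$id[iL],
    right_marker_id = if (is.na(iR)) NA_character_ else map$id[iR],
    start_bp = start_bp, end_bp = end_bp,
    length_bp = span_bp(start_bp, end_bp),
    length_cM = marker_cM_at(map, end_bp) - marker_cM_at(map, start_bp),
    consensus_alleles = consensus,
    n_haplotypes = length(rows),
    focal = focal, missing_policy = missing_policy,
    max_mismatch_haps = max_mismatch_haps), class = "core_haplotype")
}

# cM at a bp position, linear interpolation within the map
marker_cM_at <- function(map, bp) {
  stats::approx(map$pos_bp, map$pos_cM, xout = bp, rule = 2,
                ties = "ordered")$y
}

#' @export
print.core_haplotype <- function(x, ...) {
  cat(sprintf("Core haplotype: %s:%d-%d (%s, %.4f cM), %d markers, %d haplotypes\n",
              x$focal$chrom, x$start_bp, x$end_bp, format_kb(x$length_bp),
              x$length_cM, length(x$consensus_alleles), x$n_haplotypes))
  cat(sprintf("Boundary markers: %s - %s\n", x$left_marker_id,
              x$right_marker_id))
  invisible(x)
}

#' Select the mutation-bearing haplotype of each carrier sample
#'
#' On real diploid data the mutation is known from clinical testing per
#' sample, not per chromosome. For each carrier sample this picks the
#' haplotype agreeing with the current carrier consensus at more markers
#' (inside an optional window around the focal position), iterating consensus
#' and selection to a fixed point; ties keep the sample's first haplotype.
#'
#' @param panel a [haplotype_panel()].
#' @param carrier_samples sample ids known to carry the mutation.
#' @param focal a [focal_mutation()] (only used with `window_bp`).
#' @param window_bp optional `c(start, end)` restricting the comparison to
#'   markers near the focal mutation (default: all markers).
#' @param max_iter iteration cap (default 10).
#' @return The panel with `carries_mutation` set on one haplotype per carrier
#'   sample.
#' @export
assign_carrier_haplotypes <- function(panel, carrier_samples, focal = NULL,
                                      window_bp = NULL, max_iter = 10L) {
  missing_samples <- setdiff(carrier_samples, panel$sample_of_haplotype)
  if (length(missing_samples)) {
    stop("carrier sample(s) not in panel: ",
         paste(missing_samples, collapse = ", "))
  }
  cols <- seq_len(ncol(panel$alleles))
  if (!is.null(window_bp)) {
    cols <- which(panel$map$pos_bp >= window_bp[1L] &
                    panel$map$pos_bp <= window_bp[2L])
    if (!length(cols)) stop("window contains no markers")
  }
  pair_rows <- lapply(carrier_samples, function(s) {
    which(panel$sample_of_haplotype == s)
  })
  chosen <- vapply(pair_rows, `[`, integer(1L), 1L)  # start with h1
  for (it in seq_len(max_iter)) {
    a <- panel$alleles[chosen, cols, drop = FALSE]
    n1 <- colSums(a == 1L, na.rm = TRUE)
    n0 <- colSums(a == 0L, na.rm = TRUE)
    cons <- ifelse(n1 > n0, 1L, 0L)
    new_chosen <- vapply(pair_rows, function(rows) {
      score <- vapply(rows, function(r) {
        sum(panel$alleles[r, cols] == cons, na.rm = TRUE)
      }, integer(1L))
      rows[which.max(score)]  # ties -> first haplotype
    }, integer(1L))
    if (identical(new_chosen, chosen)) break
    chosen <- new_chosen
  }
  panel$carries_mutation <- seq_len(nrow(panel$alleles)) %in% chosen
  panel
}

#' Shared segment between two haplotypes around the focal mutation
#'
#' Extends outward from the markers flanking the focal position and closes
#' each side at the last agreeing marker before the first opposing-allele
#' site. With `max_mismatches > 0` a total budget of opposing-allele sites is
#' tolerated across both sides; markers are consumed outward in order of
#' genetic distance from the focal position (ties: left first) and a side
#' closes once accepting its next mismatch would exceed the remaining budget.
#'
#' @param panel a [haplotype_panel()].
#' @param focal a [focal_mutation()].
#' @param hap_i,hap_j haplotype row ids.
#' @param max_mismatches total opposing-allele sites tolerated (default 0).
#' @param missing_policy `"ignore"` (default) skips markers where either
#'   haplotype is missing; `"mismatch"` treats them as opposing.
#' @return A list of class `"shared_segment"` with `hap_i`, `hap_j`,
#'   `start_bp`, `end_bp`, `length_bp`, `length_cM`,
#'   `n_mismatches_allowed`.
#' @export
pairwise_shared_segment <- function(panel, focal, hap_i, hap_j,
                                    max_mismatches = 0L,
                                    missing_policy = c("ignore", "mismatch")) {
  missing_policy <- match.arg(missing_policy)
  map <- panel$map
  ids <- haplotype_ids(panel)
  i <- match(hap_i, ids); j <- match(hap_j, ids)
  if (is.na(i) || is.na(j)) stop("haplotype id not in panel")
  if (i == j) {
    warning("identical haplotype ids; segment spans the whole map")
    return(new_shared_segment(hap_i, hap_j, map$pos_bp[1L],
                              map$pos_bp[nrow(map)], map, max_mismatches))
  }
  ai <- panel$alleles[i, ]; aj <- panel$alleles[j, ]
  # per-marker status: 0 match (or skipped missing), 1 mismatch
  status <- as.integer(ai != aj)
  if (missing_policy == "ignore") status[is.na(status)] <- 0L
  else status[is.na(status)] <- 1L
  fl <- flanking_indices(map, focal)
  focal_cM <- marker_cM_at(map, focal$pos_bp)
  res <- extend_two_sided(status, fl, map$pos_cM, focal_cM, max_mismatches)
  start_bp <- if (is.na(res$iL)) focal$pos_bp else map$pos_bp[res$iL]
  end_bp <- if (is.na(res$iR)) focal$pos_bp else map$pos_bp[res$iR]
  new_shared_segment(hap_i, hap_j, start_bp, end_bp, map, max_mismatches)
}

# greedy symmetric outward extension with a shared mismatch budget.
# status: 0/1 per marker; fl: flanking indices; returns last matching marker
# index on each side (NA if none).
extend_two_sided <- function(status, fl, pos_cM, focal_cM, budget) {
  n <- length(status)
  iL <- NA_integer_; iR <- NA_integer_
  l <- fl[["left"]]; r <- fl[["right"]]
  if (!is.na(l) && !is.na(r) && l == r) {
    # single marker at the focal position: treat as the first right candidate
    l <- l - 1L
    if (l < 1L) l <- NA_integer_
  }
  open_l <- !is.na(l); open_r <- !is.na(r)
  while (open_l || open_r) {
    dl <- if (open_l) focal_cM - pos_cM[l] else Inf
    dr <- if (open_r) pos_cM[r] - focal_cM else Inf
    if (dl <= dr) {
      if (status[l] == 1L) {
        if (budget > 0L) budget <- budget - 1L else open_l <- FALSE
      } else iL <- l
      if (open_l) { l <- l - 1L; if (l < 1L) open_l <- FALSE }
    } else {
      if (status[r] == 1L) {
        if (budget > 0L) budget <- budget - 1L else open_r <- FALSE
      } else iR <- r
      if (open_r) { r <- r + 1L; if (r > n) open_r <- FALSE }
    }
  }
  list(iL = iL, iR = iR)
}

new_shared_segment <- function(hap_i, hap_j, start_bp, end_bp, map,
                               max_mismatches) {
  structure(list(hap_i = hap_i, hap_j = hap_j,
                 start_bp = start_bp, end_bp = end_bp,
                 length_bp = span_bp(start_bp, end_bp),
                 length_cM = marker_cM_at(map, end_bp) -
                   marker_cM_at(map, start_bp),
                 n_mismatches_allowed = max_mismatches),
            class = "shared_segment")
}

#' @export
print.shared_segment <- function(x, ...) {
  cat(sprintf("Shared segment %s ~ %s: %d-%d (%s, %.4f cM)\n", x$hap_i,
              x$hap_j, x$start_bp, x$end_bp, format_kb(x$length_bp),
              x$length_cM))
  invisible(x)
}

#' All-pairs shared segments among mutation-bearing haplotypes
#'
#' @inheritParams pairwise_shared_segment
#' @param hap_ids haplotypes to compare; defaults to all mutation-bearing
#'   haplotypes (all haplotypes if none flagged).
#' @return A data frame of class `"shared_segments"` with one row per
#'   unordered pair: `hap_i`, `hap_j`, `start_bp`, `end_bp`, `length_bp`,
#'   `length_cM`.
#' @export
all_shared_segments <- function(panel, focal, hap_ids = NULL,
                                max_mismatches = 0L,
                                missing_policy = c("ignore", "mismatch")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(hap_ids)) {
    hap_ids <- haplotype_ids(panel)[panel$carries_mutation]
    if (length(hap_ids) == 0L) hap_ids <- haplotype_ids(panel)
  }
  pairs <- utils::combn(hap_ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    s <- pairwise_shared_segment(panel, focal, pairs[1L, k], pairs[2L, k],
                                 max_mismatches = max_mismatches,
                                 missing_policy = missing_policy)
    data.frame(hap_i = s$hap_i, hap_j = s$hap_j, start_bp = s$start_bp,
               end_bp = s$end_bp, length_bp = s$length_bp,
               length_cM = s$length_cM, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "hap_ids") <- hap_ids
  class(out) <- c("shared_segments", "data.frame")
  out
}

#' Single-linkage grouping of haplotypes by shared length
#'
#' Haplotypes are joined whenever their pairwise shared segment is at least
#' `min_shared_cM` long; connected components are the haplotype groups
#' (the "mutation haplotypes"). Cluster labels are assigned in order of each
#' cluster's smallest member id.
#'
#' @param segments output of [all_shared_segments()].
#' @param min_shared_cM linkage threshold in centimorgans.
#' @return Named integer vector: cluster label per haplotype id.
#' @export
group_haplotypes <- function(segments, min_shared_cM) {
  ids <- attr(segments, "hap_ids")
  if (is.null(ids)) ids <- sort(unique(c(segments$hap_i, segments$hap_j)))
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  link <- segments$length_cM >= min_shared_cM
  for (k in which(link)) {
    ri <- find(match(segments$hap_i[k], ids))
    rj <- find(match(segments$hap_j[k], ids))
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_along(ids), find, integer(1L))
  # label clusters by smallest member id (lexicographic)
  first_member <- vapply(unique(roots), function(r) min(ids[roots == r]),
                         character(1L))
  lab <- order(order(first_member))
  cluster <- lab[match(roots, unique(roots))]
  names(cluster) <- ids
  cluster
}

#' Write core haplotype and segments as BED and TSV
#'
#' BED output is 0-based half-open (converted from the package's 1-based
#' closed coordinates).
#'
#' @param core a `core_haplotype`.
#' @param segments a `shared_segments` data frame (optional).
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @param chrom chromosome name for the BED records.
#' @return Invisibly, a list of the paths written.
#' @export
write_core_outputs <- function(core, segments = NULL, bed_path = NULL,
                               tsv_path = NULL, chrom = core$focal$chrom) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = chrom, start = core$start_bp - 1L,
                      end = core$end_bp, name = "core_haplotype")
    if (!is.null(segments)) {
      bed <- rbind(bed, data.frame(chrom = chrom,
                                   start = segments$start_bp - 1L,
                                   end = segments$end_bp,
                                   name = paste(segments$hap_i,
                                                segments$hap_j, sep = "~")))
    }
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    tsv <- data.frame(record = "core", hap_i = NA, hap_j = NA,
                      start_bp = core$start_bp, end_bp = core$end_bp,
                      length_bp = core$length_bp, length_cM = core$length_cM)
    if (!is.null(segments)) {
      tsv <- rbind(tsv, data.frame(record = "segment",
                                   hap_i = segments$hap_i,
                                   hap_j = segments$hap_j,
                                   start_bp = segments$start_bp,
                                   end_bp = segments$end_bp,
                                   length_bp = segments$length_bp,
                                   length_cM = segments$length_cM))
    }
    utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}
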