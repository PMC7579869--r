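#' GRCh37 length of chromosome 17 in base pairs
#'
#' Default chromosome length used when a marker map does not carry an explicit
#' value. All coordinates in this package are 1-based GRCh37 positions.
#'
#' @export
CHR17_LENGTH_BP <- 81195210L

#' Construct a marker map
#'
#' A marker map is the coordinate backbone shared by every analysis stage:
#' an ordered set of biallelic markers on one chromosome with physical (bp)
#' and genetic (cM) positions.
#'
#' @param id character vector of marker identifiers.
#' @param chrom single chromosome name; all markers must lie on it.
#' @param pos_bp integer vector of 1-based physical positions, strictly
#'   increasing.
#' @param pos_cM numeric vector of genetic map positions in centimorgans,
#'   non-decreasing and non-negative. If `NULL`, positions are derived from
#'   `pos_bp` at a constant `rate_cM_per_Mb`.
#' @param ref,alt single-character allele codes per marker (defaults "A"/"B"
#'   for array-style abstract alleles).
#' @param chrom_length_bp chromosome length in bp; defaults to
#'   [CHR17_LENGTH_BP] for chr17 and to the last marker position otherwise.
#' @param chrom_length_cM chromosome genetic length; defaults to the last
#'   marker's cM position.
#' @param rate_cM_per_Mb constant recombination rate used only when `pos_cM`
#'   is `NULL` (default 1 cM/Mb).
#'
#' @return A `data.frame` of class `"marker_map"` with columns `id`, `chrom`,
#'   `pos_bp`, `pos_cM`, `ref`, `alt` and attributes `chrom_length_bp`,
#'   `chrom_length_cM`.
#' @export
marker_map <- function(id, chrom, pos_bp, pos_cM = NULL, ref = NULL, alt = NULL,
                       chrom_length_bp = NULL, chrom_length_cM = NULL,
                       rate_cM_per_Mb = 1.0) {
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicate marker ids")
  if (length(pos_bp) != n) stop("pos_bp length does not match id")
  pos_bp <- as.integer(pos_bp)
  if (any(pos_bp < 1L)) stop("pos_bp must be >= 1")
  if (is.unsorted(pos_bp, strictly = TRUE)) {
    stop("pos_bp must be strictly increasing")
  }
  if (length(chrom) != 1L) stop("chrom must be a single chromosome name")
  if (is.null(pos_cM)) {
    pos_cM <- (pos_bp - pos_bp[1L]) * rate_cM_per_Mb / 1e6
  }
  if (length(pos_cM) != n) stop("pos_cM length does not match id")
  if (any(!is.finite(pos_cM)) || any(pos_cM < 0)) {
    stop("pos_cM must be finite and non-negative")
  }
  if (is.unsorted(pos_cM)) stop("pos_cM must be non-decreasing")
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("B", n)
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L)) {
    stop("alleles must be single characters")
  }
  if (any(ref == alt)) stop("ref and alt alleles must be distinct")
  if (is.null(chrom_length_bp)) {
    chrom_length_bp <- if (chrom %in% c("17", "chr17")) CHR17_LENGTH_BP else pos_bp[n]
  }
  chrom_length_bp <- as.integer(chrom_length_bp)
  if (chrom_length_bp < pos_bp[n]) {
    stop("chrom_length_bp smaller than the last marker position")
  }
  if (is.null(chrom_length_cM)) chrom_length_cM <- pos_cM[n]
  map <- data.frame(id = unname(as.character(id)), chrom = unname(chrom),
                    pos_bp = unname(pos_bp), pos_cM = unname(as.numeric(pos_cM)),
                    ref = unname(ref), alt = unname(alt),
                    stringsAsFactors = FALSE)
  attr(map, "chrom_length_bp") <- chrom_length_bp
  attr(map, "chrom_length_cM") <- as.numeric(chrom_length_cM)
  class(map) <- c("marker_map", "data.frame")
  map
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("Marker map: %d markers on %s (%s - %s bp, %.3f - %.3f cM)\n",
              nrow(x), x$chrom[1L], format(x$pos_bp[1L], big.mark = ","),
              format(x$pos_bp[nrow(x)], big.mark = ","),
              x$pos_cM[1L], x$pos_cM[nrow(x)]))
  cat(sprintf("Chromosome length: %s bp, %.2f cM\n",
              format(attr(x, "chrom_length_bp"), big.mark = ","),
              attr(x, "chrom_length_cM")))
  invisible(x)
}

#' Define the focal mutation
#'
#' @param chrom chromosome name.
#' @param pos_bp 1-based physical position of the mutation.
#' @param name mutation name.
#' @return A list of class `"focal_mutation"`.
#' @export
focal_mutation <- function(chrom = "17", pos_bp = 41244000L,
                           name = "BRCA1 c.3331_3334delCAAG") {
  pos_bp <- as.integer(pos_bp)
  if (pos_bp < 1L) stop("pos_bp must be >= 1")
  structure(list(chrom = chrom, pos_bp = pos_bp, name = name),
            class = "focal_mutation")
}

#' @export
print.focal_mutation <- function(x, ...) {
  cat(sprintf("Focal mutation: %s at %s:%s\n", x$name, x$chrom,
              format(x$pos_bp, big.mark = ",")))
  invisible(x)
}

# Check a focal position against a map; outside the typed interval is allowed
# but flagged so callers can warn.
focal_within_map <- function(focal, map) {
  focal$pos_bp >= map$pos_bp[1L] && focal$pos_bp <= map$pos_bp[nrow(map)]
}

#' Read a HapMap-format recombination map
#'
#' Parses a tab- or space-separated recombination map with a header and three
#' numeric columns (physical position, recombination rate in cM/Mb, cumulative
#' genetic position in cM; a leading chromosome column is tolerated) and
#' returns a position-to-cM interpolator.
#'
#' @param path path to the map file. Lines starting with `#` are skipped.
#' @return A function `f(pos_bp)` of class `"genetic_map"` returning
#'   centimorgan positions: linear interpolation between map points, linear
#'   extrapolation with the terminal interval rates beyond the ends (floored
#'   at 0 cM below the map start).
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  num <- vapply(tab, is.numeric, logical(1L))
  if (sum(num) < 3L) stop("genetic map needs 3 numeric columns (pos, rate, cM)")
  tab <- tab[, which(num)[seq.int(sum(num) - 2L, sum(num))], drop = FALSE]
  genetic_map_interpolator(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Build a position-to-cM interpolator from map points
#'
#' @param pos_bp physical positions of the map points (strictly increasing).
#' @param rate_cM_per_Mb recombination rate in each interval starting at the
#'   corresponding position (the last value is the extrapolation rate beyond
#'   the map end; the first is also used below the map start).
#' @param cM cumulative genetic position at each point, non-decreasing.
#' @return Interpolator function as in [read_genetic_map()].
#' @export
genetic_map_interpolator <- function(pos_bp, rate_cM_per_Mb, cM) {
  if (is.unsorted(pos_bp, strictly = TRUE)) stop("map positions must increase")
  if (is.unsorted(cM)) stop("cumulative cM must be non-decreasing")
  if (any(rate_cM_per_Mb < 0)) stop("rates must be non-negative")
  pos <- as.numeric(pos_bp)
  cm <- as.numeric(cM)
  rate <- as.numeric(rate_cM_per_Mb)
  n <- length(pos)
  f <- function(query_bp) {
    q <- as.numeric(query_bp)
    out <- stats::approx(pos, cm, xout = q, rule = 2, ties = "ordered")$y
    below <- !is.na(q) & q < pos[1L]
    above <- !is.na(q) & q > pos[n]
    if (any(below)) {
      out[below] <- pmax(0, cm[1L] - (pos[1L] - q[below]) * rate[1L] / 1e6)
    }
    if (any(above)) {
      out[above] <- cm[n] + (q[above] - pos[n]) * rate[n] / 1e6
    }
    out
  }
  class(f) <- c("genetic_map", "function")
  f
}

#' Read a PLINK .map file
#'
#' Four whitespace-separated columns: chromosome, marker id, genetic position
#' (cM, may be 0 for "unknown"), physical position (bp).
#'
#' @param path path to the `.map` file.
#' @param genetic_map optional interpolator from [read_genetic_map()] used to
#'   fill genetic positions when the cM column is all zero (or when
#'   `override_cM = TRUE`).
#' @param override_cM replace the file's cM column with interpolated values.
#' @inheritParams marker_map
#' @return A [marker_map()].
#' @export
read_plink_map <- function(path, genetic_map = NULL, override_cM = FALSE,
                           chrom_length_bp = NULL, rate_cM_per_Mb = 1.0) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("PLINK .map needs 4 columns")
  names(tab)[1:4] <- c("chrom", "id", "cM", "bp")
  ord <- order(tab$bp)
  tab <- tab[ord, , drop = FALSE]
  cm <- as.numeric(tab$cM)
  if (override_cM || all(cm == 0)) {
    if (!is.null(genetic_map)) {
      cm <- genetic_map(tab$bp)
    } else {
      cm <- (tab$bp - tab$bp[1L]) * rate_cM_per_Mb / 1e6
    }
  }
  marker_map(id = tab$id, chrom = as.character(tab$chrom[1L]),
             pos_bp = tab$bp, pos_cM = cm, chrom_length_bp = chrom_length_bp)
}

#' Physical span of a marker interval
#'
#' Interval lengths follow the difference convention `end - start` (not
#' `end - start + 1`): the printed coordinate pairs of conserved-haplotype
#' boundaries reproduce their printed kb/Mb lengths only under this
#' convention.
#'
#' @param start_bp,end_bp 1-based interval boundaries, `end_bp >= start_bp`.
#' @return Integer span in base pairs.
#' @export
#' @examples
#' span_bp(41223094, 41487451)  # 264357, i.e. "264.4 kb"
span_bp <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) stop("end_bp must be >= start_bp")
  as.integer(round(end_bp - start_bp))
}

#' Format a bp span in kilobases (1 decimal)
#' @param bp span in base pairs.
#' @return e.g. `"264.4 kb"`.
#' @export
format_kb <- function(bp) sprintf("%.1f kb", bp / 1e3)

#' Format a bp span in megabases (1 decimal)
#' @param bp span in base pairs.
#' @return e.g. `"3.9 Mb"`.
#' @export
format_mb <- function(bp) sprintf("%.1f Mb", bp / 1e6)

#' Format a bp span as approximate kb (nearest 10 kb)
#' @param bp span in base pairs.
#' @return e.g. `"~290 kb"`.
#' @export
format_approx_kb <- function(bp) sprintf("~%d kb", as.integer(round(bp / 1e4) * 10))
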