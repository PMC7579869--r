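#' Genetic distance matrix from pairwise shared segments
#'
#' The distance between two mutation haplotypes is the chromosome length
#' minus the length they share around the focal mutation:
#' `d_ij = chrom_length - shared_ij`, `d_ii = 0`.
#'
#' @param segments output of [all_shared_segments()].
#' @param chrom_length chromosome length in the chosen units (bp or cM);
#'   defaults to the GRCh37 chr17 length in bp.
#' @param units `"bp"` (default) or `"cM"`; selects which shared-length
#'   column is subtracted.
#' @return A symmetric numeric matrix of class `"distance_matrix"` with zero
#'   diagonal and a `"units"` attribute.
#' @export
distance_matrix <- function(segments, chrom_length = CHR17_LENGTH_BP,
                            units = c("bp", "cM")) {
  units <- match.arg(units)
  shared <- if (units == "bp") segments$length_bp else segments$length_cM
  if (any(shared > chrom_length)) {
    stop("shared length exceeds chromosome length")
  }
  ids <- attr(segments, "hap_ids")
  if (is.null(ids)) ids <- sort(unique(c(segments$hap_i, segments$hap_j)))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(segments$hap_i, ids)
  j <- match(segments$hap_j, ids)
  d[cbind(i, j)] <- chrom_length - shared
  d[cbind(j, i)] <- chrom_length - shared
  attr(d, "units") <- units
  class(d) <- c("distance_matrix", "matrix", "array")
  d
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean: iteratively merges the
#' closest pair of clusters, averaging distances weighted by cluster sizes.
#' Node heights are half the merge distance, so the tree is ultrametric. Ties
#' are broken deterministically by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest member).
#'
#' @param d symmetric distance matrix with labelled rows/columns (a
#'   [distance_matrix()] or any numeric matrix), `n >= 2`, no `NaN`/`NA`.
#' @return A rooted ultrametric tree of class `"phylo"` (ape).
#' @export
upgma <- function(d) {
  d <- unclass(d)
  attr(d, "units") <- NULL
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 leaves")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("L", seq_len(n))
  }
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    stop("distance matrix must be symmetric")
  }
  labels <- rownames(d)
  # active clusters: newick fragment, size, height, smallest member label
  nwk <- labels
  size <- rep(1L, n)
  height <- rep(0, n)
  smallest <- labels
  active <- rep(TRUE, n)
  dm <- d
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (a in idx) for (b in idx) {
      if (a >= b) next
      key <- sort(c(smallest[a], smallest[b]))
      tol <- 1e-12 * max(1, abs(dm[a, b]))
      take <- if (is.null(best)) TRUE
        else if (dm[a, b] < best_d - tol) TRUE
        else if (abs(dm[a, b] - best_d) <= tol &&
                 (key[1L] < best_key[1L] ||
                  (key[1L] == best_key[1L] && key[2L] < best_key[2L]))) TRUE
        else FALSE
      if (take) {
        best <- c(a, b); best_d <- dm[a, b]; best_key <- key
      }
    }
    a <- best[1L]; b <- best[2L]
    h <- best_d / 2
    nwk_new <- sprintf("(%s:%.12g,%s:%.12g)", nwk[a], h - height[a],
                       nwk[b], h - height[b])
    # size-weighted average linkage to every other active cluster
    others <- setdiff(idx, c(a, b))
    if (length(others)) {
      dm[a, others] <- (size[a] * dm[a, others] + size[b] * dm[b, others]) /
        (size[a] + size[b])
      dm[others, a] <- dm[a, others]
    }
    nwk[a] <- nwk_new
    size[a] <- size[a] + size[b]
    height[a] <- h
    smallest[a] <- min(smallest[a], smallest[b])
    active[b] <- FALSE
  }
  tree <- ape::read.tree(text = paste0(nwk[which(active)], ";"))
  tree
}

#' Write a tree in Newick format
#' @param tree a `phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#' @param d a [distance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  labels <- rownames(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(labels[i], width = -10L),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param d a [distance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  out <- data.frame(id = rownames(d), unclass(d)[, , drop = FALSE],
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The two deepest clades of a rooted tree
#'
#' Returns the leaf sets of the two children of the root — the partition the
#' deepest split induces.
#'
#' @param tree a rooted `phylo` tree.
#' @return A list of two character vectors of leaf labels.
#' @export
root_bipartition <- function(tree) {
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  lapply(kids, function(k) {
    if (k <= n_tip) return(tree$tip.label[k])
    ape::extract.clade(tree, k)$tip.label
  })
}
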