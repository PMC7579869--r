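# Independent brute-force oracles and fixture builders shared by the tests.
# These deliberately re-derive each quantity from first principles rather
# than reusing package internals.

# --- fixtures -----------------------------------------------------------

# random small phased panel: all haplotypes flagged as mutation carriers
build_random_panel <- function(n_hap = 6L, n_markers = 30L, miss_rate = 0.1,
                               region = c(1e6, 2e6), seed = 1L) {
  set.seed(seed)
  pos <- sort(sample.int(region[2] - region[1] - 1L, n_markers)) + region[1]
  map <- marker_map(id = paste0("m", seq_len(n_markers)), chrom = "17",
                    pos_bp = pos, chrom_length_bp = 81195210L)
  a <- matrix(sample(0:1, n_hap * n_markers, replace = TRUE), n_hap)
  if (miss_rate > 0) a[matrix(runif(length(a)) < miss_rate, n_hap)] <- NA
  if (n_hap %% 2L == 1L) {
    a <- rbind(a, sample(0:1, n_markers, replace = TRUE))
    n_hap <- n_hap + 1L
  }
  haplotype_panel(map, a, rep(paste0("S", seq_len(n_hap / 2L)), each = 2L),
                  carries_mutation = TRUE)
}

random_focal <- function(map) {
  pos <- map$pos_bp
  focal_mutation("17", pos_bp = round(mean(range(pos))), name = "sim")
}

# --- HWE enumeration oracle --------------------------------------------

# full enumeration of the conditional distribution of the heterozygote count
# given allele counts, using the complete closed-form probability (with all
# constant terms, unlike the implementation which normalises a kernel)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(1)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  prob <- vapply(hs, function(h) {
    nAA2 <- (nA - h) / 2
    naa2 <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(nAA2) - lfactorial(h) - lfactorial(naa2) +
          h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  p_obs <- prob[hs == n_Aa]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

# --- core-haplotype / segment oracles ----------------------------------

# per-column conserved flags, re-derived
oracle_conserved_flags <- function(alleles, missing_policy, max_mm) {
  apply(alleles, 2L, function(col) {
    if (missing_policy == "mismatch" && anyNA(col)) return(FALSE)
    obs <- col[!is.na(col)]
    if (!length(obs)) return(TRUE)
    min(sum(obs == 0), sum(obs == 1)) <= max_mm
  })
}

# brute-force core scan: maximal conserved run around the flanking markers,
# located through run-length encoding rather than outward stepping
oracle_core <- function(panel, focal, missing_policy = "ignore", max_mm = 0L) {
  map <- panel$map
  a <- panel$alleles[panel$carries_mutation, , drop = FALSE]
  ok <- oracle_conserved_flags(a, missing_policy, max_mm)
  fL <- if (any(map$pos_bp <= focal$pos_bp)) max(which(map$pos_bp <= focal$pos_bp)) else NA
  fR <- if (any(map$pos_bp >= focal$pos_bp)) min(which(map$pos_bp >= focal$pos_bp)) else NA
  iL <- NA_integer_
  if (!is.na(fL) && ok[fL]) {
    bad <- which(!ok[seq_len(fL)])
    iL <- if (length(bad)) max(bad) + 1L else 1L
  }
  iR <- NA_integer_
  if (!is.na(fR) && ok[fR]) {
    bad <- which(!ok[seq.int(fR, length(ok))])
    iR <- if (length(bad)) fR + min(bad) - 2L else length(ok)
  }
  start <- if (is.na(iL)) focal$pos_bp else map$pos_bp[iL]
  end <- if (is.na(iR)) focal$pos_bp else map$pos_bp[iR]
  list(start_bp = start, end_bp = end)
}

# naive re-implementation of the greedy symmetric extension with a total
# mismatch budget: walk all markers in order of genetic distance from the
# focal position (left wins ties) and track each side's last match
oracle_segment <- function(panel, focal, hap_i, hap_j, max_mm = 0L,
                           missing_policy = "ignore") {
  map <- panel$map
  ids <- rownames(panel$alleles)
  ai <- panel$alleles[match(hap_i, ids), ]
  aj <- panel$alleles[match(hap_j, ids), ]
  mism <- as.integer(ai != aj)
  mism[is.na(mism)] <- if (missing_policy == "ignore") 0L else 1L
  focal_cM <- approx(map$pos_bp, map$pos_cM, xout = focal$pos_bp, rule = 2)$y
  side <- ifelse(map$pos_bp <= focal$pos_bp, "L", "R")
  # a marker exactly at the focal position is scanned from the right
  at_focal <- map$pos_bp == focal$pos_bp
  side[at_focal] <- "R"
  dist <- abs(map$pos_cM - focal_cM)
  ord <- order(dist, side != "L")  # left first on exact ties
  open <- c(L = TRUE, R = TRUE)
  last <- c(L = NA_integer_, R = NA_integer_)
  budget <- max_mm
  for (idx in ord) {
    s <- side[idx]
    if (!open[[s]]) next
    if (mism[idx] == 1L) {
      if (budget > 0L) budget <- budget - 1L else open[[s]] <- FALSE
    } else last[[s]] <- idx
  }
  start <- if (is.na(last[["L"]])) focal$pos_bp else map$pos_bp[last[["L"]]]
  end <- if (is.na(last[["R"]])) focal$pos_bp else map$pos_bp[last[["R"]]]
  list(start_bp = start, end_bp = end)
}

# --- UPGMA oracle -------------------------------------------------------

# naive UPGMA recomputing every cluster distance as the arithmetic mean of
# ORIGINAL leaf distances; returns the cophenetic matrix implied by the
# merge sequence
oracle_upgma_cophenetic <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL; best_d <- Inf
    for (a in seq_len(m - 1L)) for (b in seq.int(a + 1L, m)) {
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    A <- clusters[[best[1L]]]; B <- clusters[[best[2L]]]
    coph[A, B] <- best_d
    coph[B, A] <- best_d
    clusters[[best[1L]]] <- c(A, B)
    clusters[[best[2L]]] <- NULL
  }
  coph
}

# random ultrametric matrix via random agglomeration at increasing heights
random_ultrametric <- function(n, seed) {
  set.seed(seed)
  labels <- paste0("t", seq_len(n))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  h <- 0
  while (length(clusters) > 1L) {
    h <- h + runif(1, 0.5, 2)
    pick <- sample.int(length(clusters), 2L)
    A <- clusters[[pick[1L]]]; B <- clusters[[pick[2L]]]
    coph[A, B] <- 2 * h
    coph[B, A] <- 2 * h
    clusters[[pick[1L]]] <- c(A, B)
    clusters[[pick[2L]]] <- NULL
  }
  coph
}

# cophenetic matrix of a phylo tree, aligned to given labels
tree_cophenetic <- function(tree, labels) {
  cc <- ape::cophenetic.phylo(tree)
  cc[labels, labels]
}
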