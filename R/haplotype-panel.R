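#' Construct a phased haplotype panel
#'
#' The panel holds the phased allele matrix over carrier and control
#' chromosomes. Alleles are coded 0 (ref) / 1 (alt) with `NA` as the dedicated
#' missing sentinel; every diploid sample contributes exactly two haplotype
#' rows.
#'
#' @param map a [marker_map()].
#' @param alleles integer matrix `[n_haplotypes x n_markers]` over `{0, 1, NA}`.
#'   Row names, if absent, are derived from sample ids as `<sample>_h1/_h2`.
#' @param sample_of_haplotype character vector mapping each haplotype row to
#'   its sample id; each sample must occur exactly twice.
#' @param population per-haplotype population label (e.g. country); recycled
#'   from length 1.
#' @param carries_mutation logical per haplotype: does this chromosome carry
#'   the focal mutation?
#' @return A list of class `"haplotype_panel"`.
#' @export
haplotype_panel <- function(map, alleles, sample_of_haplotype,
                            population = "NA", carries_mutation = FALSE) {
  stopifnot(inherits(map, "marker_map"))
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != nrow(map)) {
    stop("allele matrix has ", ncol(alleles), " columns but map has ",
         nrow(map), " markers")
  }
  bad <- !is.na(alleles) & !(alleles %in% c(0L, 1L))
  if (any(bad)) stop("alleles must be 0, 1 or NA")
  n_hap <- nrow(alleles)
  sample_of_haplotype <- as.character(sample_of_haplotype)
  if (length(sample_of_haplotype) != n_hap) {
    stop("sample_of_haplotype length does not match allele rows")
  }
  counts <- table(sample_of_haplotype)
  if (any(counts != 2L)) {
    stop("each diploid sample must contribute exactly 2 haplotypes; offending: ",
         paste(names(counts)[counts != 2L], collapse = ", "))
  }
  population <- rep_len(as.character(population), n_hap)
  carries_mutation <- rep_len(as.logical(carries_mutation), n_hap)
  if (is.null(rownames(alleles)) || anyDuplicated(rownames(alleles))) {
    idx <- stats::ave(seq_len(n_hap), sample_of_haplotype, FUN = seq_along)
    rownames(alleles) <- paste0(sample_of_haplotype, "_h", idx)
  }
  structure(list(map = map, alleles = alleles,
                 sample_of_haplotype = sample_of_haplotype,
                 population = population,
                 carries_mutation = carries_mutation),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d haplotypes (%d samples) x %d markers on %s\n",
              nrow(x$alleles), length(unique(x$sample_of_haplotype)),
              ncol(x$alleles), x$map$chrom[1L]))
  cat(sprintf("Mutation-bearing haplotypes: %d; missing allele calls: %.3f%%\n",
              sum(x$carries_mutation),
              100 * mean(is.na(x$alleles))))
  invisible(x)
}

#' Haplotype ids of a panel
#' @param panel a [haplotype_panel()].
#' @return Character vector of haplotype row ids.
#' @export
haplotype_ids <- function(panel) rownames(panel$alleles)

#' Subset a panel to selected haplotypes
#' @param panel a [haplotype_panel()].
#' @param hap_ids haplotype row ids or logical/integer index.
#' @return A list with the panel's fields restricted to those rows (sample
#'   pairing is not enforced on the subset).
#' @export
subset_haplotypes <- function(panel, hap_ids) {
  if (is.character(hap_ids)) hap_ids <- match(hap_ids, haplotype_ids(panel))
  out <- panel
  out$alleles <- panel$alleles[hap_ids, , drop = FALSE]
  out$sample_of_haplotype <- panel$sample_of_haplotype[hap_ids]
  out$population <- panel$population[hap_ids]
  out$carries_mutation <- panel$carries_mutation[hap_ids]
  # sample pairing no longer guaranteed, so drop the class contract
  class(out) <- "haplotype_subset"
  out
}

#' Read a phased single-chromosome VCF into a haplotype panel
#'
#' All GT fields must use the phased separator `|`; each sample yields two
#' haplotype rows in GT order. Multiallelic records and duplicated positions
#' are rejected.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param genetic_map optional interpolator from [read_genetic_map()] for
#'   genetic positions; without it a constant `rate_cM_per_Mb` is used.
#' @param carrier_haplotypes optional character vector of haplotype ids
#'   (`<sample>_h1`/`_h2`) to flag as mutation-bearing.
#' @param chrom_length_bp passed to [marker_map()].
#' @param rate_cM_per_Mb fallback constant recombination rate.
#' @return A [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, genetic_map = NULL, carrier_haplotypes = NULL,
                            chrom_length_bp = NULL, rate_cM_per_Mb = 1.0) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0L) stop("VCF contains no records")
  if (length(unique(fix[, "CHROM"])) != 1L) {
    stop("VCF must contain exactly one chromosome")
  }
  pos <- as.integer(fix[, "POS"])
  if (anyDuplicated(pos)) {
    stop("duplicate position(s) in VCF: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record(s) at position(s): ",
         paste(pos[multi], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1L, dimnames = list(NULL, colnames(v@gt)[-1L]))
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    bad <- which(unphased)[1L]
    bad_row <- (bad - 1L) %% nrow(gt) + 1L
    bad_col <- (bad - 1L) %/% nrow(gt) + 1L
    stop(sprintf("unphased genotype at %s:%d sample %s",
                 fix[bad_row, "CHROM"], pos[bad_row], colnames(gt)[bad_col]))
  }
  ord <- order(pos)
  pos <- pos[ord]
  fix <- fix[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", pos[noid])
  cm <- if (is.null(genetic_map)) NULL else genetic_map(pos)
  map <- marker_map(id = ids, chrom = fix[1L, "CHROM"], pos_bp = pos,
                    pos_cM = cm, ref = substr(fix[, "REF"], 1L, 1L),
                    alt = substr(fix[, "ALT"], 1L, 1L),
                    chrom_length_bp = chrom_length_bp,
                    rate_cM_per_Mb = rate_cM_per_Mb)
  samples <- colnames(gt)
  parse_hap <- function(allele_str) {
    a <- suppressWarnings(as.integer(allele_str))
    a[allele_str == "."] <- NA_integer_
    a
  }
  a1 <- parse_hap(sub("\\|.*$", "", gt))
  a2 <- parse_hap(sub("^.*\\|", "", gt))
  n_m <- length(pos)
  alleles <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = n_m)
  for (s in seq_along(samples)) {
    alleles[2L * s - 1L, ] <- a1[(s - 1L) * n_m + seq_len(n_m)]
    alleles[2L * s, ] <- a2[(s - 1L) * n_m + seq_len(n_m)]
  }
  rownames(alleles) <- paste0(rep(samples, each = 2L), "_h", c(1L, 2L))
  carries <- if (is.null(carrier_haplotypes)) FALSE else
    rownames(alleles) %in% carrier_haplotypes
  haplotype_panel(map, alleles, rep(samples, each = 2L),
                  carries_mutation = carries)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased GT columns reconstructing the panel's
#' haplotype pairs; `NA` alleles become `.`.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  map <- panel$map
  samples <- unique(panel$sample_of_haplotype)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", map$chrom[1L],
                      attr(map, "chrom_length_bp")),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  fmt <- function(a) ifelse(is.na(a), ".", as.character(a))
  gt_cols <- vapply(samples, function(s) {
    rows <- which(panel$sample_of_haplotype == s)
    paste0(fmt(panel$alleles[rows[1L], ]), "|", fmt(panel$alleles[rows[2L], ]))
  }, character(nrow(map)))
  if (is.null(dim(gt_cols))) gt_cols <- matrix(gt_cols, nrow = nrow(map))
  body <- paste(map$chrom, map$pos_bp, map$id, map$ref, map$alt, ".", "PASS",
                ".", "GT",
                apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct a genotype table (alt-allele dosage)
#'
#' @param map a [marker_map()].
#' @param genotypes integer matrix `[n_samples x n_markers]` over
#'   `{0, 1, 2, NA}`.
#' @return A list of class `"genotype_table"`.
#' @export
genotype_table <- function(map, genotypes) {
  stopifnot(inherits(map, "marker_map"))
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (ncol(genotypes) != nrow(map)) stop("genotype columns must match map markers")
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(genotypes)) && nrow(genotypes) > 0L) {
    rownames(genotypes) <- paste0("S", seq_len(nrow(genotypes)))
  }
  structure(list(map = map, genotypes = genotypes), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d samples x %d markers (%.2f%% missing)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Collapse a phased panel into a genotype table
#'
#' Dosage is the sum of the two haplotype alleles of each sample; a missing
#' allele on either haplotype yields a missing dosage (missing policy:
#' propagate).
#'
#' @param panel a [haplotype_panel()].
#' @return A [genotype_table()].
#' @export
panel_to_genotypes <- function(panel) {
  samples <- unique(panel$sample_of_haplotype)
  g <- t(vapply(samples, function(s) {
    rows <- which(panel$sample_of_haplotype == s)
    panel$alleles[rows[1L], ] + panel$alleles[rows[2L], ]
  }, integer(ncol(panel$alleles))))
  rownames(g) <- samples
  genotype_table(panel$map, g)
}
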