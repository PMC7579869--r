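# End-to-end driver: qc -> core -> segments -> tree -> date -> ancestry,
# reading a key-value (YAML) config, with deterministic per-stage seeding and
# a manifest that makes every output traceable to the config.

#' Default pipeline configuration
#'
#' @param outdir run directory.
#' @param seed global seed, fanned out to per-stage child seeds (see
#'   [stage_seed()]).
#' @param ... overrides for any default entry.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir, seed = 1L, ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    # inputs; when NULL the synthetic-study driver generates them
    vcf = NULL, map = NULL, ancestry = NULL, simulate = TRUE,
    carrier_samples = NULL,
    sim = list(),
    focal = list(chrom = "17", pos_bp = 41244000L,
                 name = "BRCA1 c.3331_3334delCAAG"),
    qc = list(min_call_rate = 0.95, maf_min = 0.05, hwe_p_min = 1e-5),
    core = list(missing_policy = "ignore", max_mismatch_haps = 0L),
    grouping = list(min_shared_cM = 1.0),
    tree = list(units = "bp"),
    dating = list(window_bp = c(39040105L, 43387103L), n_iter = 50000L,
                  n_burn = 5000L, prior = c(1, 500), max_mismatches = 2L),
    chrom_length_bp = CHR17_LENGTH_BP,
    generation_years = 20)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline config from a YAML file
#'
#' @param path YAML file; keys mirror [pipeline_config()] arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$outdir)) stop("config must set outdir")
  do.call(pipeline_config, raw)
}

#' Derive a deterministic per-stage child seed
#'
#' `stage_seed(seed, k) = (seed * 48271 + k) mod (2^31 - 1)`: a fixed affine
#' fan-out so each stage is individually reproducible from the global seed.
#'
#' @param seed global integer seed.
#' @param stage_index integer stage index (1-based).
#' @return Integer child seed.
#' @export
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 48271 + stage_index) %% 2147483647)
}

validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!isTRUE(config$simulate)) {
    for (p in c("vcf", "map")) {
      if (is.null(config[[p]]) || !file.exists(config[[p]])) {
        stop("config error: input path '", p, "' missing or nonexistent")
      }
    }
  }
  qc <- config$qc
  if (qc$min_call_rate < 0 || qc$min_call_rate > 1 ||
      qc$maf_min < 0 || qc$maf_min > 0.5 ||
      qc$hwe_p_min < 0 || qc$hwe_p_min > 1) {
    stop("config error: QC thresholds out of range")
  }
  invisible(TRUE)
}

# write a file atomically: .partial until complete
stage_write <- function(writer, path) {
  partial <- paste0(path, ".partial")
  writer(partial)
  file.rename(partial, path)
  path
}

run_stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  msg <- sprintf("[%s] done in %.2fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
  res
}

#' Run the founder-haplotype analysis pipeline
#'
#' Executes QC, core-haplotype detection, all-pairs shared segments and
#' grouping, the UPGMA tree, mutation dating (moment and MCMC) and the
#' ancestry comparison, writing every stage's outputs plus a manifest to the
#' run directory. With `simulate = TRUE` (default) the synthetic-study driver
#' first generates the inputs under `outdir/inputs`. Reruns with an identical
#' config are bit-identical.
#'
#' @param config a [pipeline_config()] (or path handled by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the run directory, the manifest, and the
#'   stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  focal <- focal_mutation(config$focal$chrom, config$focal$pos_bp,
                          config$focal$name)

  inputs <- NULL
  if (isTRUE(config$simulate)) {
    sim <- run_stage("simulate", log_con, {
      sim_args <- config$sim
      sim_args$seed <- stage_seed(config$seed, 1L)
      sim_args$focal <- focal
      cfg <- do.call(sim_config, sim_args)
      simulate_carrier_panel(cfg)
    })
    tracks <- run_stage("simulate_ancestry", log_con, {
      set.seed(stage_seed(config$seed, 2L))
      panel <- sim$panel
      is_carrier_hap <- panel$sample_of_haplotype %in%
        unique(panel$sample_of_haplotype[panel$carries_mutation])
      props <- stats::setNames(c(0.6, 0.3, 0.1), ANCESTRY_LABELS)
      props_carrier <- stats::setNames(c(0.8, 0.15, 0.05), ANCESTRY_LABELS)
      t_ctl <- simulate_ancestry_tracks(sum(!is_carrier_hap), panel$map,
                                        props)
      t_car <- simulate_ancestry_tracks(sum(is_carrier_hap), panel$map,
                                        props_carrier)
      labels <- rbind(t_car$labels, t_ctl$labels)
      ancestry_tracks(panel$map, labels,
                      c(panel$sample_of_haplotype[is_carrier_hap],
                        panel$sample_of_haplotype[!is_carrier_hap]),
                      c(rep(TRUE, sum(is_carrier_hap)),
                        rep(FALSE, sum(!is_carrier_hap))))
    })
    inputs <- write_simulation(sim, file.path(config$outdir, "inputs"),
                               tracks = tracks)
    panel <- sim$panel
  } else {
    panel <- run_stage("read_inputs", log_con, {
      gmap <- read_genetic_map(config$map)
      p <- read_phased_vcf(config$vcf, genetic_map = gmap,
                           chrom_length_bp = config$chrom_length_bp)
      if (!any(p$carries_mutation)) {
        if (!is.null(config$carrier_samples)) {
          p <- assign_carrier_haplotypes(p, config$carrier_samples, focal)
        } else {
          # no flags and no carrier list: treat every haplotype as
          # mutation-bearing (carriers-only input)
          p$carries_mutation <- rep(TRUE, nrow(p$alleles))
        }
      }
      p
    })
    tracks <- if (!is.null(config$ancestry)) {
      read_ancestry_tracks(config$ancestry, panel$map)
    } else NULL
  }

  qc_res <- run_stage("qc", log_con, {
    r <- qc_panel(panel, min_call_rate = config$qc$min_call_rate,
                  maf_min = config$qc$maf_min,
                  hwe_p_min = config$qc$hwe_p_min)
    stage_write(function(p) write_qc_report(r$report, p),
                file.path(config$outdir, "qc_report.tsv"))
    r
  })
  panel_qc <- qc_res$panel

  core <- run_stage("core", log_con, {
    find_core_haplotype(panel_qc, focal,
                        missing_policy = config$core$missing_policy,
                        max_mismatch_haps = config$core$max_mismatch_haps)
  })
  segments <- run_stage("segments", log_con, {
    s <- all_shared_segments(panel_qc, focal,
                             missing_policy = config$core$missing_policy)
    stage_write(function(p) write_core_outputs(core, s, bed_path = p),
                file.path(config$outdir, "core_segments.bed"))
    stage_write(function(p) write_core_outputs(core, s, tsv_path = p),
                file.path(config$outdir, "core_segments.tsv"))
    s
  })
  groups <- group_haplotypes(segments, config$grouping$min_shared_cM)

  tree <- run_stage("tree", log_con, {
    chrom_len <- if (config$tree$units == "bp") config$chrom_length_bp
                 else attr(panel_qc$map, "chrom_length_cM")
    d <- distance_matrix(segments, chrom_length = chrom_len,
                         units = config$tree$units)
    tr <- upgma(d)
    stage_write(function(p) write_newick(tr, p),
                file.path(config$outdir, "tree.nwk"))
    stage_write(function(p) write_distance_tsv(d, p),
                file.path(config$outdir, "distances.tsv"))
    tr
  })

  dating <- run_stage("date", log_con, {
    ref <- consensus_haplotype(panel_qc)
    window <- config$dating$window_bp
    if (!is.null(window)) {
      in_win <- panel_qc$map$pos_bp >= window[1L] &
        panel_qc$map$pos_bp <= window[2L]
      if (!any(in_win)) window <- NULL  # map does not cover the default window
    }
    extents <- extract_extents(panel_qc, ref, focal, window_bp = window,
                               max_mismatches = config$dating$max_mismatches)
    mom <- moment_age(extents, generation_years = config$generation_years)
    mcmc <- mcmc_age(extents, prior_g = config$dating$prior,
                     n_iter = config$dating$n_iter,
                     n_burn = config$dating$n_burn,
                     seed = stage_seed(config$seed, 5L),
                     generation_years = config$generation_years)
    out <- list(
      moment = list(estimate = mom$estimate, ci95 = mom$ci95,
                    years = mom$years),
      mcmc = list(estimate = mcmc$estimate, ci95 = mcmc$ci95,
                  years = mcmc$years, acceptance_rate = mcmc$acceptance_rate,
                  n_iter = config$dating$n_iter, n_burn = config$dating$n_burn,
                  prior = config$dating$prior,
                  seed = stage_seed(config$seed, 5L)))
    stage_write(function(p) jsonlite::write_json(out, p, auto_unbox = TRUE,
                                                 digits = NA),
                file.path(config$outdir, "age.json"))
    stage_write(function(p) {
      utils::write.table(data.frame(iteration = seq_along(mcmc$samples),
                                    g = mcmc$samples),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(config$outdir, "age_trace.tsv"))
    list(moment = mom, mcmc = mcmc)
  })

  ancestry <- NULL
  if (!is.null(tracks)) {
    ancestry <- run_stage("ancestry", log_con, {
      cmp <- compare_carrier_ancestry(tracks, ancestry = "EUR")
      out <- unclass(cmp)
      stage_write(function(p) jsonlite::write_json(out, p, auto_unbox = TRUE,
                                                   digits = NA),
                  file.path(config$outdir, "ancestry.json"))
      cmp
    })
  }

  manifest <- run_stage("manifest", log_con, {
    outs <- setdiff(list.files(config$outdir, recursive = TRUE,
                               full.names = TRUE),
                    c(file.path(config$outdir, "manifest.json"), log_path))
    digests <- as.list(tools::md5sum(outs))
    names(digests) <- sub(paste0("^", config$outdir, "/?"), "", names(digests))
    m <- list(package = "foundertrace",
              version = as.character(utils::packageVersion("foundertrace")),
              seed = config$seed,
              stage_seeds = stats::setNames(
                as.list(vapply(1:5, function(k) stage_seed(config$seed, k),
                               integer(1L))),
                c("simulate", "ancestry_sim", "qc", "core", "date")),
              config = config_as_list(config),
              outputs_md5 = digests)
    stage_write(function(p) jsonlite::write_json(m, p, auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE),
                file.path(config$outdir, "manifest.json"))
    m
  })

  invisible(list(outdir = config$outdir, manifest = manifest,
                 panel = panel_qc, qc = qc_res$report, core = core,
                 segments = segments, groups = groups, tree = tree,
                 dating = dating, ancestry = ancestry))
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$focal <- lapply(cfg$focal, function(v) v)
  rapply(cfg, function(v) v, how = "replace")
}
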