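# Allele age estimation from recombination-driven decay of the founder
# haplotype. Under a star genealogy every carrier lineage descends
# independently from the founder over g generations, so each one-sided
# retained genetic extent is Exponential(rate = g) in Morgans, censored at
# the edge of the genotyped window.

#' Demographic model parameters
#'
#' Houses the demographic quantities used for mutation dating: population
#' sizes, generations, the per-generation exponential growth rate
#' `d = ln(P_t/P_o)/g`, and the proportion `f` of mutation-carrying
#' chromosomes.
#'
#' @param P_t current population size.
#' @param P_o initial (founding) population size.
#' @param g generations between `P_o` and `P_t`.
#' @param generation_years years per generation (default 20).
#' @param d per-generation growth rate; computed from `(P_t, P_o, g)` when
#'   not supplied.
#' @param f proportion of mutation-carrying chromosomes (optional).
#' @return A list of class `"demographic_model"`.
#' @export
demographic_model <- function(P_t, P_o, g, generation_years = 20,
                              d = NULL, f = NULL) {
  if (P_t <= 0 || P_o <= 0 || g <= 0) stop("P_t, P_o and g must be positive")
  if (is.null(d)) d <- growth_rate(P_t, P_o, g)
  structure(list(P_t = P_t, P_o = P_o, g = g,
                 generation_years = generation_years, d = d, f = f),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model: P_t = %.4g, P_o = %.4g over g = %.4g generations\n",
              x$P_t, x$P_o, x$g))
  cat(sprintf("Growth rate d = %.4f per generation; %g years per generation\n",
              x$d, x$generation_years))
  if (!is.null(x$f)) cat(sprintf("Carrier-chromosome proportion f = %.3g\n", x$f))
  invisible(x)
}

#' Per-generation population growth rate
#'
#' `d = ln(P_t / P_o) / g`: the exponential rate linking the founding
#' population size to the current one across `g` generations.
#'
#' @param P_t current population size.
#' @param P_o initial population size.
#' @param g number of generations between the two.
#' @return The growth rate per generation.
#' @export
#' @examples
#' growth_rate(51e6, 1000, 26.05)  # 0.416..., i.e. 0.42 at 2 decimals
growth_rate <- function(P_t, P_o, g) {
  if (any(c(P_t, P_o, g) <= 0)) stop("P_t, P_o and g must be positive")
  log(P_t / P_o) / g
}

#' Convert years to generations
#' @param years elapsed years.
#' @param generation_years years per generation (default 20).
#' @return `years / generation_years`.
#' @export
#' @examples
#' years_to_generations(521)  # 26.05
years_to_generations <- function(years, generation_years = 20) {
  if (any(generation_years <= 0)) stop("generation_years must be positive")
  years / generation_years
}

#' Convert generations to years
#' @param g generations.
#' @param generation_years years per generation (default 20).
#' @return `g * generation_years`.
#' @export
#' @examples
#' generations_to_years(24.8)  # 496
generations_to_years <- function(g, generation_years = 20) {
  if (any(generation_years <= 0)) stop("generation_years must be positive")
  g * generation_years
}

#' Proportion of mutation-carrying chromosomes
#'
#' Definitional form: heterozygous carriers contribute one mutant chromosome
#' each, so `f = prevalence * mutation_share / 2`, where `mutation_share` is
#' the fraction of carriers attributable to the focal mutation.
#'
#' @param carrier_prevalence population prevalence of carriers, in (0, 1].
#' @param mutation_share fraction of carriers bearing the focal mutation
#'   (default 1).
#' @return `f`, the mutation-carrying chromosome proportion.
#' @export
carrier_chromosome_fraction <- function(carrier_prevalence,
                                        mutation_share = 1.0) {
  if (any(carrier_prevalence < 0 | carrier_prevalence > 1)) {
    stop("carrier_prevalence must be in [0, 1]")
  }
  carrier_prevalence * mutation_share / 2
}

#' Majority-consensus haplotype of the mutation carriers
#'
#' Per-marker majority allele across mutation-bearing haplotypes (missing
#' ignored; ties -> 0), used as the ancestral reference when the true founder
#' haplotype is unknown.
#'
#' @param panel a [haplotype_panel()].
#' @return Integer vector of consensus alleles (length = markers).
#' @export
consensus_haplotype <- function(panel) {
  rows <- which(panel$carries_mutation)
  if (length(rows) == 0L) rows <- seq_len(nrow(panel$alleles))
  a <- panel$alleles[rows, , drop = FALSE]
  n1 <- colSums(a == 1L, na.rm = TRUE)
  n0 <- colSums(a == 0L, na.rm = TRUE)
  out <- ifelse(n1 > n0, 1L, 0L)
  out[n1 + n0 == 0L] <- NA_integer_
  as.integer(out)
}

#' Extract one-sided retained haplotype extents
#'
#' For each mutation-bearing haplotype, measures the genetic distance (in
#' Morgans) from the focal position to the last marker matching the ancestral
#' reference before the first opposing-allele marker, separately on each
#' side. An extent is censored when the haplotype matches the reference all
#' the way to the window edge.
#'
#' @param panel a [haplotype_panel()].
#' @param reference ancestral reference alleles over all map markers (e.g.
#'   the simulation founder haplotype or [consensus_haplotype()]); a
#'   `core_haplotype` is accepted and its consensus is completed with the
#'   panel consensus outside the core.
#' @param focal a [focal_mutation()].
#' @param window_bp optional `c(start, end)` restricting the analysis to a
#'   dating window (default: the whole map).
#' @param missing_policy `"ignore"` (default) skips missing alleles;
#'   `"mismatch"` lets a missing call terminate the match.
#' @param max_mismatches per-side budget of opposing-allele markers tolerated
#'   before the extent is closed (default 0: the extent ends at the last
#'   matching marker before the first opposing marker). A small budget makes
#'   the extents robust to isolated genotyping errors on dense marker maps,
#'   where a single miscall would otherwise truncate the retained segment.
#' @return A data frame of class `"extent_data"` with columns `hap_id`,
#'   `side` (`"left"`/`"right"`), `extent_morgans`, `censored`.
#' @export
extract_extents <- function(panel, reference, focal, window_bp = NULL,
                            missing_policy = c("ignore", "mismatch"),
                            max_mismatches = 0L) {
  missing_policy <- match.arg(missing_policy)
  map <- panel$map
  if (inherits(reference, "core_haplotype")) {
    ref <- consensus_haplotype(panel)
    idx <- match(names(reference$consensus_alleles), map$id)
    ref[idx] <- reference$consensus_alleles
  } else {
    ref <- as.integer(reference)
    if (length(ref) != nrow(map)) stop("reference length must match map")
  }
  keep <- rep(TRUE, nrow(map))
  if (!is.null(window_bp)) {
    keep <- map$pos_bp >= window_bp[1L] & map$pos_bp <= window_bp[2L]
    if (!any(keep)) stop("dating window contains no markers")
  }
  idx_keep <- which(keep)
  sub_pos_cM <- map$pos_cM[idx_keep]
  focal_cM <- marker_cM_at(map, focal$pos_bp)
  rows <- which(panel$carries_mutation)
  if (length(rows) == 0L) stop("no mutation-bearing haplotypes")
  fl_left <- if (any(map$pos_bp[idx_keep] <= focal$pos_bp))
    max(which(map$pos_bp[idx_keep] <= focal$pos_bp)) else NA_integer_
  fl_right <- if (any(map$pos_bp[idx_keep] >= focal$pos_bp))
    min(which(map$pos_bp[idx_keep] >= focal$pos_bp)) else NA_integer_
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    a <- panel$alleles[rows[k], idx_keep]
    match_ref <- a == ref[idx_keep]
    if (missing_policy == "ignore") match_ref[is.na(match_ref)] <- TRUE
    else match_ref[is.na(match_ref)] <- FALSE
    # left side
    ext <- function(indices, edge_idx) {
      if (length(indices) == 0L || is.na(edge_idx)) {
        return(c(extent = 0, censored = 0))
      }
      mism <- which(!match_ref[indices])
      if (length(mism) <= max_mismatches) {
        last_idx <- indices[length(indices)]
        return(c(extent = abs(sub_pos_cM[last_idx] - focal_cM) / 100,
                 censored = 1))
      }
      stop_mism <- mism[max_mismatches + 1L]  # closing opposing marker
      last_match <- which(match_ref[indices][seq_len(stop_mism)])
      if (length(last_match) == 0L) return(c(extent = 0, censored = 0))
      last_idx <- indices[max(last_match)]
      c(extent = abs(sub_pos_cM[last_idx] - focal_cM) / 100, censored = 0)
    }
    li <- if (is.na(fl_left)) integer() else seq.int(fl_left, 1L)
    # avoid double-counting a marker exactly at the focal position
    ri_start <- if (!is.na(fl_left) && !is.na(fl_right) && fl_left == fl_right)
      fl_right else fl_right
    ri <- if (is.na(fl_right)) integer()
      else seq.int(ri_start, length(idx_keep))
    L <- ext(li, fl_left)
    R <- ext(ri, fl_right)
    out[[k]] <- data.frame(
      hap_id = rep(haplotype_ids(panel)[rows[k]], 2L),
      side = c("left", "right"),
      extent_morgans = c(L[["extent"]], R[["extent"]]),
      censored = as.logical(c(L[["censored"]], R[["censored"]])),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (all(res$extent_morgans == 0 & !res$censored)) {
    warning("no carrier matches the reference at any flanking marker")
  }
  class(res) <- c("extent_data", "data.frame")
  res
}

#' Fit a mutation-age model to haplotype extents
#'
#' Central fitting function. Under the star-genealogy approximation each
#' one-sided retained extent `x` (Morgans) is Exponential with rate `g`
#' (generations), censored at the window edge. `method = "moment"` returns
#' the closed-form maximum-likelihood estimate; `method = "mcmc"` samples the
#' posterior of `g` under a uniform prior by Metropolis-Hastings (see
#' [mcmc_age()] for details and the optional population-growth correction).
#'
#' @param extents an `extent_data` data frame from [extract_extents()].
#' @param method `"moment"` or `"mcmc"`.
#' @param generation_years years per generation for the years conversion.
#' @param ... passed to [moment_age()] or [mcmc_age()].
#' @return An object of class `"mutation_age"` with components `estimate`
#'   (posterior mean / MLE of `g`), `ci95`, `years`, `method`, `k`
#'   (uncensored extents), `total_morgans`, and for MCMC fits `samples`,
#'   `acceptance_rate`, `n_iterations`, `n_burn_in`, `seed`.
#' @seealso [moment_age()], [mcmc_age()]
#' @export
mutation_age <- function(extents, method = c("moment", "mcmc"),
                         generation_years = 20, ...) {
  method <- match.arg(method)
  switch(method,
         moment = moment_age(extents, generation_years = generation_years, ...),
         mcmc = mcmc_age(extents, generation_years = generation_years, ...))
}

#' Moment (maximum-likelihood) age estimate
#'
#' With `k` uncensored one-sided extents and total extent sum `T` Morgans
#' (censored extents included at their censoring bound), the star-genealogy
#' MLE is `g = k / T`; the 95% CI comes from the chi-square distribution of
#' the gamma-distributed total, `[qchisq(.025, 2k), qchisq(.975, 2k)] / (2T)`.
#'
#' @inheritParams mutation_age
#' @return A `"mutation_age"` object (see [mutation_age()]).
#' @export
moment_age <- function(extents, generation_years = 20) {
  stopifnot(is.data.frame(extents))
  k <- sum(!extents$censored)
  total <- sum(extents$extent_morgans)
  if (total <= 0) stop("total extent is zero; cannot estimate age")
  if (k == 0L) {
    warning("all extents censored; returning an upper bound only")
    est <- NA_real_
    ci <- c(0, stats::qchisq(0.95, df = 2) / (2 * total))
  } else {
    est <- k / total
    ci <- stats::qchisq(c(0.025, 0.975), df = 2 * k) / (2 * total)
  }
  new_mutation_age(estimate = est, ci95 = ci, method = "moment",
                   generation_years = generation_years, k = k,
                   total_morgans = total)
}

# log-likelihood of g (no-growth star genealogy): k*ln(g) - g*T
star_loglik <- function(g, k, total) k * log(g) - g * total

# log-likelihood with growth correction: lineage depth t ~ d*exp(-d*(g-t)) on
# [0, g] (normalised); per-extent density integrates over t by Gauss-Legendre
# quadrature with n_nodes nodes.
growth_loglik <- function(g, x, censored, d, quad) {
  t_nodes <- g * quad$x          # quad on [0, 1]
  w <- g * quad$w
  prior_t <- d * exp(-d * (g - t_nodes)) / (1 - exp(-d * g))
  # matrix [extents x nodes]
  et <- exp(-outer(x, t_nodes))
  dens_unc <- et %*% (w * prior_t * t_nodes)
  dens_cen <- et %*% (w * prior_t)
  dens <- ifelse(censored, dens_cen, dens_unc)
  if (any(dens <= 0)) return(-Inf)
  sum(log(dens))
}

#' Bayesian MCMC age estimate
#'
#' Metropolis-Hastings sampling of the mutation age `g` under the
#' star-genealogy extent likelihood (density `g*exp(-g*x)` for uncensored
#' extents, survivor `exp(-g*x)` for censored ones) and a uniform prior on
#' `g`. Proposals are Gaussian on `log g`, with the step size adapted during
#' burn-in toward an acceptance rate of 0.2-0.5 and frozen afterwards. The
#' optional growth mode integrates the lineage depth `t` over a
#' growing-population intra-allelic genealogy approximation
#' (`t ~ d*exp(-d*(g-t))` truncated to `[0, g]`, Gauss-Legendre quadrature).
#'
#' @inheritParams mutation_age
#' @param prior_g uniform prior bounds on `g` in generations
#'   (default `c(1, 500)`).
#' @param n_iter total iterations (default 1e6).
#' @param n_burn burn-in iterations discarded (default 1e5).
#' @param seed RNG seed (required for reproducibility).
#' @param model optional [demographic_model()]; when supplied (and
#'   `growth = TRUE`) its growth rate `d` activates the growth-corrected
#'   likelihood.
#' @param growth use the growth-corrected likelihood (default: `TRUE` iff
#'   `model` is supplied).
#' @param n_quad quadrature nodes for the growth mode (minimum 64).
#' @param thin keep every `thin`-th post-burn-in sample (default 1).
#' @return A `"mutation_age"` object (see [mutation_age()]).
#' @export
mcmc_age <- function(extents, prior_g = c(1, 500), n_iter = 1e6,
                     n_burn = 1e5, seed = 1L, model = NULL,
                     growth = !is.null(model), n_quad = 64L, thin = 1L,
                     generation_years = 20) {
  stopifnot(is.data.frame(extents))
  if (any(prior_g <= 0) || prior_g[2L] <= prior_g[1L]) {
    stop("prior bounds must be positive with low < high")
  }
  if (growth && is.null(model)) stop("growth mode requires a demographic model")
  if (growth && n_quad < 64L) stop("growth mode requires >= 64 quadrature nodes")
  x <- extents$extent_morgans
  censored <- extents$censored
  k <- sum(!censored)
  total <- sum(x)
  quad <- NULL
  if (growth) {
    gl <- pracma::gaussLegendre(n_quad, 0, 1)
    quad <- list(x = gl$x, w = gl$w)
  }
  loglik <- function(g) {
    if (length(x) == 0L) return(0)
    if (growth) growth_loglik(g, x, censored, model$d, quad)
    else star_loglik(g, k, total)
  }
  set.seed(seed)
  lo <- log(prior_g[1L]); hi <- log(prior_g[2L])
  y <- (lo + hi) / 2                      # state: log g
  # uniform prior on g => density on y = log g proportional to exp(y)
  logpost <- function(y) {
    if (y < lo || y > hi) return(-Inf)
    ll <- loglik(exp(y))
    if (!is.finite(ll)) {
      if (is.nan(ll)) stop("non-finite likelihood at g = ", exp(y))
      return(-Inf)
    }
    ll + y
  }
  lp <- logpost(y)
  if (!is.finite(lp)) stop("prior excludes all posterior mass at the start state")
  step <- 0.5
  keep <- floor((n_iter - n_burn) / thin)
  samples <- numeric(keep)
  n_acc <- 0L
  acc_window <- 0L
  s_idx <- 0L
  for (it in seq_len(n_iter)) {
    prop <- y + stats::rnorm(1L, 0, step)
    lp_prop <- logpost(prop)
    if (log(stats::runif(1L)) < lp_prop - lp) {
      y <- prop; lp <- lp_prop
      if (it > n_burn) n_acc <- n_acc + 1L
      acc_window <- acc_window + 1L
    }
    if (it <= n_burn && it %% 100L == 0L) {
      rate <- acc_window / 100
      if (rate < 0.2) step <- step * 0.8
      else if (rate > 0.5) step <- step * 1.25
      acc_window <- 0L
    }
    if (it > n_burn && (it - n_burn) %% thin == 0L) {
      s_idx <- s_idx + 1L
      if (s_idx <= keep) samples[s_idx] <- exp(y)
    }
  }
  samples <- samples[seq_len(s_idx)]
  est <- mean(samples)
  ci <- unname(stats::quantile(samples, c(0.025, 0.975), names = FALSE))
  new_mutation_age(estimate = est, ci95 = ci, method = "mcmc",
                   generation_years = generation_years, k = k,
                   total_morgans = total, samples = samples,
                   acceptance_rate = n_acc / (n_iter - n_burn),
                   n_iterations = n_iter, n_burn_in = n_burn, seed = seed,
                   prior_g = prior_g, growth = growth,
                   d = if (growth) model$d else NULL)
}

new_mutation_age <- function(estimate, ci95, method, generation_years, k,
                             total_morgans, ...) {
  structure(c(list(estimate = estimate, ci95 = ci95,
                   years = estimate * generation_years,
                   years_ci95 = ci95 * generation_years,
                   method = method, generation_years = generation_years,
                   k = k, total_morgans = total_morgans), list(...)),
            class = "mutation_age")
}

#' @export
print.mutation_age <- function(x, ...) {
  cat(sprintf("Mutation age (%s): %.1f generations (95%% CI %.1f - %.1f)\n",
              x$method, x$estimate, x$ci95[1L], x$ci95[2L]))
  cat(sprintf("  = %.0f years (95%% CI %.0f - %.0f) at %g years/generation\n",
              x$years, x$years_ci95[1L], x$years_ci95[2L],
              x$generation_years))
  invisible(x)
}

#' @export
summary.mutation_age <- function(object, ...) {
  print(object)
  cat(sprintf("Data: %d uncensored one-sided extents, total %.4f Morgans\n",
              object$k, object$total_morgans))
  if (object$method == "mcmc") {
    cat(sprintf("MCMC: %d iterations (%d burn-in), acceptance rate %.2f, seed %d\n",
                object$n_iterations, object$n_burn_in, object$acceptance_rate,
                object$seed))
    cat(sprintf("Prior: Uniform(%g, %g) generations%s\n", object$prior_g[1L],
                object$prior_g[2L],
                if (isTRUE(object$growth))
                  sprintf("; growth-corrected, d = %.3f", object$d) else ""))
  }
  invisible(object)
}

#' @export
coef.mutation_age <- function(object, ...) {
  c(g = object$estimate)
}

#' @export
confint.mutation_age <- function(object, parm = "g", level = 0.95, ...) {
  if (level != 0.95) {
    if (object$method != "mcmc") {
      a <- (1 - level) / 2
      ci <- stats::qchisq(c(a, 1 - a), df = 2 * object$k) /
        (2 * object$total_morgans)
    } else {
      a <- (1 - level) / 2
      ci <- unname(stats::quantile(object$samples, c(a, 1 - a)))
    }
  } else ci <- object$ci95
  m <- matrix(ci, nrow = 1L,
              dimnames = list("g", sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                              1 - (1 - level) / 2))))
  m
}

#' @export
logLik.mutation_age <- function(object, ...) {
  val <- star_loglik(object$estimate, object$k, object$total_morgans)
  structure(val, df = 1L, class = "logLik")
}

#' @export
plot.mutation_age <- function(x, ...) {
  if (x$method == "mcmc") {
    graphics::hist(x$samples, breaks = 60, freq = FALSE,
                   main = "Posterior of mutation age",
                   xlab = "g (generations)", ...)
    graphics::abline(v = x$estimate, col = "red", lwd = 2)
    graphics::abline(v = x$ci95, col = "red", lty = 2)
  } else {
    g <- seq(max(0.5, x$ci95[1L] / 2), x$ci95[2L] * 1.5, length.out = 400)
    ll <- star_loglik(g, x$k, x$total_morgans)
    graphics::plot(g, ll - max(ll), type = "l",
                   xlab = "g (generations)", ylab = "relative log-likelihood",
                   main = "Star-genealogy age likelihood", ...)
    graphics::abline(v = x$estimate, col = "red", lwd = 2)
    graphics::abline(v = x$ci95, col = "red", lty = 2)
  }
  invisible(x)
}

#' Simulate extent data from a fitted age model
#'
#' Draws new one-sided extents from the fitted exponential decay model
#' (uncensored; censoring depends on a window geometry the fit does not
#' retain).
#'
#' @param object a `"mutation_age"` fit.
#' @param nsim number of one-sided extents to draw.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return An `extent_data` data frame.
#' @export
simulate.mutation_age <- function(object, nsim = object$k, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rexp(nsim, rate = object$estimate)
  ids <- if (nsim) paste0("sim", seq_len(nsim)) else character(0)
  structure(data.frame(hap_id = ids,
                       side = rep_len(c("left", "right"), nsim),
                       extent_morgans = x, censored = FALSE,
                       stringsAsFactors = FALSE),
            class = c("extent_data", "data.frame"))
}
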