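make_extents <- function(x, censored = FALSE) {
  ids <- if (length(x)) paste0("h", seq_along(x)) else character(0)
  structure(data.frame(hap_id = ids,
                       side = rep_len(c("left", "right"), length(x)),
                       extent_morgans = x,
                       censored = rep_len(censored, length(x)),
                       stringsAsFactors = FALSE),
            class = c("extent_data", "data.frame"))
}

test_that("demographic arithmetic reproduces the worked values", {
  expect_equal(years_to_generations(521, 20), 26.05)
  expect_equal(round(growth_rate(51e6, 1000, 26.05), 2), 0.42)
  expect_equal(growth_rate(1000, 1000, 7), 0)
  expect_equal(growth_rate(1000, 1, 10), log(1000) / 10)
  expect_equal(generations_to_years(24.8, 20), 496)
  expect_equal(generations_to_years(36.3, 20), 726)
  expect_equal(generations_to_years(98.0, 20), 1960)
  expect_equal(years_to_generations(0, 20), 0)
  expect_equal(years_to_generations(100, 25), 4)
  expect_error(growth_rate(-1, 10, 5), "positive")
  # round trip
  g <- c(3.7, 26.05, 121)
  expect_equal(years_to_generations(generations_to_years(g, 23), 23), g)
})

test_that("carrier chromosome fraction is definitional prevalence/2 x share", {
  expect_equal(carrier_chromosome_fraction(1 / 1000), 0.0005)
  expect_equal(carrier_chromosome_fraction(0), 0)
  expect_equal(carrier_chromosome_fraction(1 / 1000, 0.52), 0.00026)
  expect_error(carrier_chromosome_fraction(2), "\\[0, 1\\]")
})

test_that("demographic model derives d when not supplied", {
  dm <- demographic_model(51e6, 1000, 26.05)
  expect_equal(dm$d, growth_rate(51e6, 1000, 26.05))
  dm2 <- demographic_model(46e6, 1000, 100, d = 0.11, f = 0.00026)
  expect_equal(dm2$d, 0.11)
  expect_error(demographic_model(0, 1, 1), "positive")
})

test_that("extent extraction recovers truth on error-free simulations", {
  for (seed in 1:6) {
    cfg <- sim_config(n_markers = 2000L, n_carriers = 30L, n_controls = 0L,
                      seed = seed, genotyping_error_rate = 0, missing_rate = 0)
    sim <- simulate_carrier_panel(cfg)
    ext <- extract_extents(sim$panel, sim$truth$founder, cfg$focal)
    expect_equal(nrow(ext), 2L * 30L)
    truth_cM <- c(rbind(sim$truth$left_extent_cM, sim$truth$right_extent_cM))
    got <- ifelse(ext$side == "left",
                  rep(sim$truth$left_extent_cM, each = 1)[match(ext$hap_id, sim$truth$carrier_hap_ids)],
                  rep(sim$truth$right_extent_cM, each = 1)[match(ext$hap_id, sim$truth$carrier_hap_ids)])
    # measured extent never exceeds truth by more than chance-match overshoot
    # and never falls short by more than one marker interval
    spacing_cM <- max(diff(sim$panel$map$pos_cM))
    low_ok <- ext$extent_morgans * 100 >= got - spacing_cM - 1e-9
    expect_true(all(low_ok | ext$censored))
    cens_truth <- ifelse(ext$side == "left",
                         sim$truth$left_censored[match(ext$hap_id, sim$truth$carrier_hap_ids)],
                         sim$truth$right_censored[match(ext$hap_id, sim$truth$carrier_hap_ids)])
    # censoring agrees with truth except where chance matching runs to the edge
    expect_true(all(ext$censored | !cens_truth))
  }
})

test_that("extent extraction handles degenerate matches", {
  map <- marker_map(paste0("m", 1:5), "17",
                    seq(41e6, by = 1e5, length.out = 5))
  focal <- focal_mutation("17", 41250000L)
  ref <- c(1L, 0L, 1L, 0L, 1L)
  # carrier identical to reference -> censored at both edges
  a <- rbind(ref, ref)
  panel <- haplotype_panel(map, a, c("S1", "S1"), carries_mutation = TRUE)
  ext <- extract_extents(panel, ref, focal)
  expect_true(all(ext$censored))
  # mismatch at the first flanking marker on the left -> left extent 0
  a2 <- rbind(ref, ref)
  a2[1L, 3L] <- 0L  # m3 is the left flank of 41250000
  panel2 <- haplotype_panel(map, a2, c("S1", "S1"), carries_mutation = TRUE)
  ext2 <- extract_extents(panel2, ref, focal)
  left1 <- ext2[ext2$hap_id == "S1_h1" & ext2$side == "left", ]
  expect_equal(left1$extent_morgans, 0)
  expect_false(left1$censored)
})

test_that("a mismatch budget makes extents robust to isolated miscalls", {
  map <- marker_map(paste0("m", 1:9), "17",
                    seq(41e6, by = 1e5, length.out = 9))
  focal <- focal_mutation("17", 41450000L)  # between m5 and m6
  ref <- rep(1L, 9)
  a <- rbind(ref, ref)
  a[1L, 7L] <- 0L  # isolated miscall on the right arm
  a[1L, 9L] <- 0L  # second opposing marker further out
  panel <- haplotype_panel(map, a, c("S1", "S1"), carries_mutation = TRUE)
  strict <- extract_extents(panel, ref, focal)
  r_strict <- strict[strict$hap_id == "S1_h1" & strict$side == "right", ]
  expect_equal(r_strict$extent_morgans * 100, map$pos_cM[6L] - 0.45)
  tol <- extract_extents(panel, ref, focal, max_mismatches = 1L)
  r_tol <- tol[tol$hap_id == "S1_h1" & tol$side == "right", ]
  # budget 1 skips the first miscall; the extent runs to m8, the last match
  # before the second opposing marker
  expect_equal(r_tol$extent_morgans * 100, map$pos_cM[8L] - 0.45)
  expect_false(r_tol$censored)
  # budget 2 absorbs both: censored at the window edge
  tol2 <- extract_extents(panel, ref, focal, max_mismatches = 2L)
  r_tol2 <- tol2[tol2$hap_id == "S1_h1" & tol2$side == "right", ]
  expect_true(r_tol2$censored)
})

test_that("moment estimator inverts single extents and scales correctly", {
  one <- make_extents(0.02)
  fit <- moment_age(one)
  expect_equal(fit$estimate, 50)
  expect_s3_class(fit, "mutation_age")
  expect_equal(unname(coef(fit)), 50)
  # doubling all extents halves the estimate
  x <- c(0.01, 0.04, 0.02, 0.03)
  expect_equal(moment_age(make_extents(2 * x))$estimate,
               moment_age(make_extents(x))$estimate / 2)
  # adding a short uncensored extent increases the estimate
  base <- moment_age(make_extents(x))$estimate
  more <- moment_age(make_extents(c(x, 0.001)))$estimate
  expect_gt(more, base)
  # all censored -> upper bound only, with warning
  expect_warning(cens <- moment_age(make_extents(c(0.05, 0.05), censored = TRUE)),
                 "censored")
  expect_true(is.na(cens$estimate))
  expect_equal(cens$ci95[1L], 0)
  expect_gt(cens$ci95[2L], 0)
})

test_that("moment CI is the chi-square interval for an exponential rate", {
  x <- c(0.01, 0.02, 0.05, 0.03, 0.04)
  fit <- moment_age(make_extents(x))
  k <- 5; total <- sum(x)
  expect_equal(fit$ci95, qchisq(c(0.025, 0.975), 2 * k) / (2 * total))
  expect_true(fit$ci95[1L] <= fit$estimate && fit$estimate <= fit$ci95[2L])
})

test_that("the star log-likelihood equals the analytic sum", {
  set.seed(2)
  x <- rexp(40, 30)
  cens <- runif(40) < 0.2
  ext <- make_extents(x, censored = cens)
  k <- sum(!cens); total <- sum(x)
  direct <- function(g) {
    sum(ifelse(cens, -g * x, log(g) - g * x))
  }
  for (g in c(5, 30, 120)) {
    expect_equal(foundertrace:::star_loglik(g, k, total), direct(g),
                 tolerance = 1e-12)
  }
  lfit <- moment_age(ext)
  expect_equal(as.numeric(logLik(lfit)), direct(lfit$estimate))
})

test_that("mcmc is seed-reproducible and recovers the prior without data", {
  empty <- make_extents(numeric(0))
  fit1 <- mcmc_age(empty, prior_g = c(1, 500), n_iter = 30000, n_burn = 3000,
                   seed = 11)
  fit2 <- mcmc_age(empty, prior_g = c(1, 500), n_iter = 30000, n_burn = 3000,
                   seed = 11)
  expect_identical(fit1$samples, fit2$samples)
  # posterior ~ Uniform(1, 500): mean 250.5 within Monte-Carlo error
  expect_lt(abs(fit1$estimate - 250.5), 25)
  expect_true(fit1$acceptance_rate > 0.05 && fit1$acceptance_rate < 0.95)
})

test_that("mcmc matches the moment estimate on informative data", {
  set.seed(4)
  x <- rexp(400, rate = 30)
  ext <- make_extents(x)
  mom <- moment_age(ext)
  fit <- mcmc_age(ext, n_iter = 30000, n_burn = 3000, seed = 5)
  # posterior sd ~ g/sqrt(k); the two point estimates agree well within it
  expect_lt(abs(fit$estimate - mom$estimate), sd(fit$samples))
  expect_true(fit$ci95[1L] < 30 && 30 < fit$ci95[2L])
})

test_that("growth-corrected mcmc runs and shifts the posterior sensibly", {
  set.seed(6)
  x <- rexp(120, rate = 25)
  ext <- make_extents(x)
  dm <- demographic_model(51e6, 1000, 26.05)
  fit <- mcmc_age(ext, n_iter = 8000, n_burn = 2000, seed = 7, model = dm)
  expect_true(is.finite(fit$estimate))
  # under growth, lineage depths are shallower than g, so the age estimate
  # exceeds the no-growth estimate
  fit0 <- mcmc_age(ext, n_iter = 8000, n_burn = 2000, seed = 7)
  expect_gt(fit$estimate, fit0$estimate)
  expect_error(mcmc_age(ext, model = dm, n_quad = 16), "64")
})

test_that("mcmc rejects impossible priors", {
  expect_error(mcmc_age(make_extents(0.02), prior_g = c(5, 2)), "low < high")
  expect_error(mcmc_age(make_extents(0.02), prior_g = c(-1, 10)), "positive")
})

test_that("mutation_age dispatches methods and simulate draws from the fit", {
  fit <- moment_age(make_extents(c(0.01, 0.02, 0.03)))
  expect_output(print(fit), "generations")
  expect_output(summary(fit), "uncensored")
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), fit$ci95)
  sims <- simulate(fit, nsim = 500, seed = 3)
  expect_s3_class(sims, "extent_data")
  expect_equal(nrow(sims), 500)
  # simulated extents have roughly the fitted mean 1/g
  expect_lt(abs(mean(sims$extent_morgans) - 1 / fit$estimate),
            3 / (fit$estimate * sqrt(500)))
})
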