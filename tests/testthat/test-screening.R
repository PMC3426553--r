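test_that("death_rate follows the complement-of-survival convention and clamps", {
  expect_equal(as.numeric(death_rate(1, 1)), 0)
  expect_equal(as.numeric(death_rate(0, 1)), 1)
  expect_equal(as.numeric(death_rate(0.2, 1)), 0.8)
  clamped <- death_rate(1.2, 1)
  expect_equal(as.numeric(clamped), 0)
  expect_equal(attr(clamped, "clamped"), 1L)
  expect_error(death_rate(0.5, 0), "positive")
  # antitone in the treated readout for a fixed denominator
  r <- as.numeric(death_rate(seq(0, 1, by = 0.1), 1))
  expect_true(all(diff(r) <= 0))
})

test_that("noiseless plates: all non-sensitizer columns identical, sensitizer shifted", {
  params <- plate_params(noise_sd = 0, sensitizer_ids = "s1", sensitizer_fold = 300,
                         baseline_ic50_nM = 22500, hill = 1.5)
  plate <- generate_viability_plate(c("a", "b", "s1"), c(0, 10, 100, 1000),
                                    params, n_experiments = 2, seed = 3)
  wide <- with(plate, tapply(readout, list(concentration_nM, clone_id), mean))
  expect_equal(wide[, "a"], wide[, "b"])
  expect_false(isTRUE(all.equal(wide[, "a"], wide[, "s1"])))
  expect_identical(attr(plate, "implanted_sensitizers"), "s1")
  expect_error(
    generate_viability_plate("a", c(10, 100), params, seed = 1),
    "include 0"
  )
})

test_that("hit calling: no hits when nothing exceeds the controls; single exceedance suffices", {
  fx <- screen_fixture(seed = 7, noise_sd = 0, fold = 60)
  # noiseless, but with no sensitizers implanted nothing can beat the wt control
  params <- plate_params(noise_sd = 0, clone_ic50_nM = c(untransduced = 14, wt_dCK = 12))
  quiet <- generate_viability_plate(c(fx$clone_ids, fx$controls), c(0, 10, 35, 70),
                                    params, n_experiments = 3, seed = 5)
  res0 <- call_hits(quiet, fx$clone_ids, fx$controls, screening_conc = 10)
  expect_equal(sum(res0$hit), 0L)

  # hand-built plate: clone beats both controls in exactly 1 of 3 experiments
  mk <- function(id, ex, conc, readout) {
    data.frame(clone_id = id, experiment_id = ex, concentration_nM = conc,
               readout = readout)
  }
  rows <- list()
  for (ex in c("e1", "e2", "e3")) {
    rows <- c(rows, list(
      mk("u", ex, 0, 1), mk("u", ex, 10, 0.7),
      mk("w", ex, 0, 1), mk("w", ex, 10, 0.6),
      mk("cl", ex, 0, 1), mk("cl", ex, 10, if (ex == "e2") 0.5 else 0.9)
    ))
  }
  plate <- do.call(rbind, rows)
  res <- call_hits(plate, "cl", c("u", "w"), screening_conc = 10, min_experiments = 1)
  expect_equal(res$n_exceed, 1L)
  expect_true(res$hit)
  res2 <- call_hits(plate, "cl", c("u", "w"), screening_conc = 10, min_experiments = 2)
  expect_false(res2$hit)
})

test_that("hit calling recovers exactly the implanted sensitizers at default noise", {
  fx <- screen_fixture(seed = 17)
  res <- call_hits(fx$plate, fx$clone_ids, fx$controls, screening_conc = 10)
  hits <- res$clone_id[res$hit]
  expect_true(all(fx$sensitizers %in% hits))
  expect_lte(length(setdiff(hits, fx$sensitizers)), 2L)
})

test_that("hit calling is invariant under clone and experiment relabeling order", {
  fx <- screen_fixture(seed = 23)
  res <- call_hits(fx$plate, fx$clone_ids, fx$controls, screening_conc = 10)
  shuffled_plate <- withr::with_seed(1, fx$plate[sample(nrow(fx$plate)), ])
  res_shuffled <- call_hits(shuffled_plate, rev(fx$clone_ids), fx$controls,
                            screening_conc = 10)
  merged <- merge(as.data.frame(res), as.data.frame(res_shuffled), by = "clone_id")
  expect_equal(merged$n_exceed.x, merged$n_exceed.y)
  expect_equal(merged$hit.x, merged$hit.y)
})

test_that("hit calling rejects plates with a missing control or concentration", {
  fx <- screen_fixture(seed = 29)
  drop_ctrl <- fx$plate[!(fx$plate$clone_id == "wt_dCK" &
                            fx$plate$experiment_id == "exp2"), ]
  expect_error(call_hits(drop_ctrl, fx$clone_ids, fx$controls, 10), "control")
  expect_error(call_hits(fx$plate, fx$clone_ids, fx$controls, 99), "absent")
  expect_error(call_hits(fx$plate, fx$clone_ids, "untransduced", 10), "two control")
})

test_that("noiseless dose-response recovery is exact to 0.1%", {
  sc <- messa_scenario()
  v <- noiseless_viability(sc$concentrations, 75, sc$hill)
  fit <- fit_dose_response(sc$concentrations, v)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 75, tolerance = 1e-3)
  expect_equal(fit$hill, sc$hill, tolerance = 1e-3)
  expect_lte(fit$bottom, fit$top)
})

test_that("flat viability is flagged unconverged with undefined IC50", {
  conc <- c(0, 10, 100, 1000)
  fit <- fit_dose_response(conc, rep(1, 4))
  expect_false(fit$converged)
  expect_true(is.na(fit$ic50))
  expect_error(fit_dose_response(c(0, 1, 2), c(1, 0.5, 0)), "4 distinct")
  expect_error(fit_dose_response(c(0, 1, 2, 3), c(1, 0.5, 0.2, 1.9)), "viability")
})

test_that("IC50 fold-changes of 60x and 300x are recovered within 1% without noise", {
  sc <- messa_scenario()
  fit_u <- fit_dose_response(sc$concentrations,
                             noiseless_viability(sc$concentrations, sc$untransduced_ic50, sc$hill))
  fit_w <- fit_dose_response(sc$concentrations,
                             noiseless_viability(sc$concentrations, sc$wt_ic50, sc$hill))
  fit_s <- fit_dose_response(sc$concentrations,
                             noiseless_viability(sc$concentrations, sc$sensitizer_ic50, sc$hill))
  expect_equal(fold_change(fit_u, fit_s, n_boot = 19, seed = 1)$fold, 300,
               tolerance = 0.01)
  expect_equal(fold_change(fit_w, fit_s, n_boot = 19, seed = 1)$fold, 60,
               tolerance = 0.01)
  expect_equal(fold_change(fit_w, fit_w, n_boot = 19, seed = 1)$fold, 1,
               tolerance = 1e-9)
})

test_that("IC50 recovery under noise: median relative error within 10% over replicates", {
  ic50 <- 75
  hill <- 1.5
  # 8 log-spaced test concentrations over 2 decades around ic50, plus the
  # 0-concentration normalization well
  conc <- c(0, 10^seq(log10(7.5), log10(750), length.out = 8))
  errs <- vapply(1:100, function(r) {
    v <- withr::with_seed(4000 + r, {
      pmin(pmax(noiseless_viability(conc, ic50, hill) + rnorm(length(conc), sd = 0.05), 0), 1.5)
    })
    fit <- fit_dose_response(conc, v)
    if (!fit$converged) return(NA_real_)
    abs(fit$ic50 - ic50) / ic50
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 0.10)
})

test_that("bootstrap fold interval is seeded, reproducible and brackets the estimate", {
  sc <- messa_scenario()
  v_w <- withr::with_seed(9, noiseless_viability(sc$concentrations, sc$wt_ic50, sc$hill) +
                            rnorm(length(sc$concentrations), sd = 0.02))
  v_s <- withr::with_seed(10, noiseless_viability(sc$concentrations, sc$sensitizer_ic50, sc$hill) +
                            rnorm(length(sc$concentrations), sd = 0.02))
  fit_w <- fit_dose_response(sc$concentrations, pmin(pmax(v_w, 0), 1.5))
  fit_s <- fit_dose_response(sc$concentrations, pmin(pmax(v_s, 0), 1.5))
  fc1 <- fold_change(fit_w, fit_s, n_boot = 99, seed = 42)
  fc2 <- fold_change(fit_w, fit_s, n_boot = 99, seed = 42)
  expect_identical(fc1, fc2)
  expect_lte(fc1$ci_low, fc1$fold)
  expect_gte(fc1$ci_high, fc1$fold)
  expect_error(fold_change(fit_w, fit_s, n_boot = 9), "seed")
})

test_that("Welch comparison matches a hand-computed oracle and handles degeneracy", {
  a <- c(0.1, 0.2, 0.15)
  b <- c(0.8, 0.9, 0.85)
  # hand computation: equal n and equal variances
  n <- 3
  s2a <- var(a)
  s2b <- var(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(s2a / n + s2b / n)
  df_hand <- (s2a / n + s2b / n)^2 /
    ((s2a / n)^2 / (n - 1) + (s2b / n)^2 / (n - 1))
  res <- compare_populations(a, b)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_lt(res$p_value, 0.001)

  expect_message(same <- compare_populations(c(1, 1), c(1, 1)), "convention")
  expect_equal(same$p_value, 1)
  expect_equal(same$t, 0)

  ident <- compare_populations(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
})

test_that("replicated populations at benchmark effect sizes separate at p < 1e-4", {
  # 9 vs 9 populations: strong sensitizer vs wild-type transgene at one
  # concentration, viability noise sd 0.05
  sc <- messa_scenario()
  conc <- 75
  v_g12 <- withr::with_seed(61, noiseless_viability(conc, sc$sensitizer_ic50, sc$hill) +
                              rnorm(9, sd = 0.05))
  v_wt <- withr::with_seed(62, noiseless_viability(conc, sc$wt_ic50, sc$hill) +
                             rnorm(9, sd = 0.05))
  res <- compare_populations(v_g12, v_wt)
  expect_lt(res$p_value, 1e-4)
})

test_that("screen_table combines hits with per-clone IC50 fits", {
  fx <- screen_fixture(seed = 37, noise_sd = 0)
  tab <- screen_table(fx$plate, fx$clone_ids[1:10], fx$controls,
                      screening_conc = 10, fit_ic50 = TRUE)
  expect_true(all(c("clone_id", "n_exceed", "hit", "ic50_nM", "fold_vs_reference")
                  %in% names(tab)))
  sens_in <- intersect(fx$sensitizers, fx$clone_ids[1:10])
  expect_true(all(tab$hit[tab$clone_id %in% sens_in]))
})
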