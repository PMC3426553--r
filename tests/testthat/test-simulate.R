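test_that("zero mutation rate leaves every clone identical to the reference", {
  ref <- fixture_reference()
  cfg <- evolution_config(mutation_rate = 0, generations = 8, population_size = 20,
                          seed = 1)
  lib <- simulate_library(cfg, ref)
  expect_true(all(lib$sequences == ref$sequence))
  expect_true(all(lib$clones$n_mutations == 0))
  expect_identical(nrow(lib$mutations), 0L)
})

test_that("identical seeds give byte-identical libraries; different seeds differ", {
  ref <- fixture_reference()
  cfg <- evolution_config(mutation_rate = 5e-3, generations = 5, population_size = 30,
                          heterozygous_virion_fraction = 0.3,
                          recombination_switch_rate = 1e-3, seed = 77)
  a <- simulate_library(cfg, ref)
  b <- simulate_library(cfg, ref)
  expect_identical(a, b)
  cfg2 <- cfg
  cfg2$seed <- 78L
  expect_false(identical(simulate_library(cfg2, ref)$sequences, a$sequences))
})

test_that("per-clone counts match the Poisson limit: mean within 3 SE, dispersion in [0.9, 1.1]", {
  ref <- random_reference(999L, seed = 3L)
  # uniform spectrum on a ~1000 nt gene, rate 1e-3, 5 cycles -> mean ~ 5
  cfg <- evolution_config(mutation_rate = 1e-3, generations = 5,
                          population_size = 10000,
                          spectrum = uniform_spectrum(ref), seed = 11)
  lib <- simulate_library(cfg, ref)
  counts <- lib$clones$n_mutations
  expected <- 999 * 5 * 1e-3
  se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  disp <- dispersion_test(counts)
  expect_gt(disp$index, 0.9)
  expect_lt(disp$index, 1.1)
})

test_that("simulator agrees with an independent site-by-site Bernoulli oracle", {
  ref <- fixture_reference(60L, seed = 21L)
  sp <- default_spectrum(ref)
  rate <- 5e-3
  gens <- 4L
  oracle <- oracle_library_counts(ref, rate, gens, 300L, sp, seed = 5)
  cfg <- evolution_config(mutation_rate = rate, generations = gens,
                          population_size = 300, spectrum = sp, seed = 6)
  sim <- simulate_library(cfg, ref)$clones$n_mutations
  # both are samples of the same process: compare means within 3 SE of the
  # difference, and dispersion of both near 1
  m_theory <- 60 * gens * rate
  se_diff <- sqrt(2 * m_theory / 300)
  expect_lt(abs(mean(oracle) - mean(sim)), 3 * se_diff)
  expect_lt(abs(mean(sim) - m_theory), 3 * sqrt(m_theory / 300))
})

test_that("mutated positions are uniform along the gene under a uniform spectrum", {
  ref <- random_reference(783L, seed = 31L)
  cfg <- evolution_config(mutation_rate = 2e-3, generations = 7,
                          population_size = 1000,
                          spectrum = uniform_spectrum(ref), seed = 13)
  lib <- simulate_library(cfg, ref)
  expect_gt(nrow(lib$mutations), 5000) # ~ 783*7*2e-3*1000 ~ 11k events
  h <- position_histogram(lib$mutations, bins = 9, cds_length = 783)
  p <- chisq.test(h$count)$p.value
  expect_gt(p, 0.01)
})

test_that("substitution spectrum of simulated libraries matches the configured mass", {
  ref <- random_reference(783L, seed = 41L)
  sp <- default_spectrum(ref)
  cfg <- evolution_config(mutation_rate = 2e-3, generations = 7,
                          population_size = 1000, spectrum = sp, seed = 17)
  lib <- simulate_library(cfg, ref)
  summ <- summarize_spectrum(lib$mutations)
  n <- summ$total
  expect_gt(n, 5000)
  p <- sp$joint["G", "A"]
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(summ$g_to_a_fraction - p), 3 * se)
})

test_that("cis-lethal mask: accepted genomes carry no mutations in the mask", {
  ref <- fixture_reference(90L, seed = 51L)
  mask <- 1:30
  cfg <- evolution_config(mutation_rate = 5e-3, generations = 6,
                          population_size = 200, cis_lethal_mask = mask, seed = 23)
  lib <- simulate_library(cfg, ref)
  expect_false(any(lib$mutations$position %in% mask))
  # the unmasked region still accumulates mutations
  expect_gt(nrow(lib$mutations), 0)
})

test_that("extinction under the mask fails loudly, naming the generation", {
  ref <- fixture_reference(30L, seed = 61L)
  cfg <- evolution_config(mutation_rate = 0.9, generations = 3,
                          population_size = 5, cis_lethal_mask = 1:30, seed = 29)
  expect_error(simulate_library(cfg, ref), "extinction.*cycle 1", ignore.case = TRUE)
})

test_that("config validation rejects out-of-range parameters and missing seeds", {
  expect_error(evolution_config(mutation_rate = 1.5, seed = 1))
  expect_error(evolution_config(mutation_rate = 1e-4), "seed")
  ref <- fixture_reference()
  cfg <- evolution_config(mutation_rate = 1e-4, generations = 2,
                          population_size = 5, cis_lethal_mask = 1000L, seed = 1)
  expect_error(simulate_library(cfg, ref), "mask")
})

test_that("applying the mutation log to the reference reproduces each clone", {
  ref <- fixture_reference(90L, seed = 71L)
  cfg <- evolution_config(mutation_rate = 8e-3, generations = 5,
                          population_size = 40, seed = 31)
  lib <- simulate_library(cfg, ref)
  for (id in lib$clones$clone_id) {
    ev <- lib$mutations[lib$mutations$clone_id == id, ]
    expect_identical(apply_mutations(ref, ev), unname(lib$sequences[[id]]))
  }
})

test_that("recombination: no-switch and identical-parent limits, 50/50 mixing", {
  a <- paste(rep("A", 10000), collapse = "")
  c_ <- paste(rep("C", 10000), collapse = "")
  off0 <- simulate_recombination(a, c_, switch_rate = 0, seed = 5)
  expect_true(off0 %in% c(a, c_))
  offsame <- simulate_recombination(a, a, switch_rate = 0.5, seed = 6)
  expect_identical(offsame, a)
  expect_error(simulate_recombination("ACGT", "ACG", 0.1, seed = 1), "equal length")
  # symmetric chain at switch_rate 0.5: stationary fraction 1/2 per parent
  off <- simulate_recombination(a, c_, switch_rate = 0.5, seed = 7)
  frac_a <- mean(strsplit(off, "")[[1]] == "A")
  se <- sqrt(0.25 / 10000) # positions are iid at switch rate 1/2
  expect_lt(abs(frac_a - 0.5), 3 * se)
})

test_that("zero generations returns the untouched plasmid-stage population", {
  ref <- fixture_reference()
  cfg <- evolution_config(mutation_rate = 1e-3, generations = 0,
                          population_size = 4, seed = 3)
  lib <- simulate_library(cfg, ref)
  expect_true(all(lib$clones$generation_label == "plasmid"))
  expect_true(all(lib$sequences == ref$sequence))
})
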