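# shared fixtures, built in code at test time

fixture_reference <- function(length = 90L, seed = 101L) {
  random_reference(length, seed = seed, name = "ref_fixture")
}

# slow, transparent oracle for the mutation-accumulation process:
# per genome, per cycle, per site, an explicit Bernoulli draw and a
# spectrum-row draw. Independent of the vectorized simulator code path.
oracle_library_counts <- function(reference, rate, generations, population,
                                  spectrum, seed) {
  codes <- match(strsplit(reference$sequence, "", fixed = TRUE)[[1L]],
                 c("A", "C", "G", "T"))
  n <- length(codes)
  withr::with_seed(seed, {
    counts <- integer(population)
    for (i in seq_len(population)) {
      g <- codes
      for (cyc in seq_len(generations)) {
        for (s in seq_len(n)) {
          b <- g[s]
          if (runif(1) < rate * spectrum$rate_weight[b]) {
            g[s] <- sample(1:4, 1, prob = spectrum$conditional[b, ])
          }
        }
      }
      counts[i] <- sum(g != codes)
    }
    counts
  })
}

# canonical dose-response scenario: untransduced vs wild-type transgene vs
# strong sensitizer, wide log-spaced grid (nM)
messa_scenario <- function() {
  list(
    concentrations = c(0, 10, 30, 100, 300, 1000, 3000, 10000, 30000, 100000),
    untransduced_ic50 = 22500,
    wt_ic50 = 4500,
    sensitizer_ic50 = 75,
    hill = 1.5
  )
}

noiseless_viability <- function(conc, ic50, hill) {
  1 / (1 + (conc / ic50)^hill)
}

# hit-calling screen fixture: 76 clones, 6 implanted sensitizers, controls
screen_fixture <- function(seed = 7L, noise_sd = 0.01, fold = 60) {
  clone_ids <- sprintf("F16_clone%04d", 1:76)
  sens <- sprintf("F16_clone%04d", c(3, 12, 25, 40, 58, 71))
  controls <- c("untransduced", "wt_dCK")
  params <- plate_params(
    noise_sd = noise_sd,
    sensitizer_ids = sens,
    sensitizer_fold = fold,
    clone_ic50_nM = c(untransduced = 14, wt_dCK = 12)
  )
  plate <- generate_viability_plate(
    c(clone_ids, controls), c(0, 10, 35, 70), params,
    n_experiments = 3L, seed = seed
  )
  list(plate = plate, clone_ids = clone_ids, sensitizers = sens,
       controls = controls)
}
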