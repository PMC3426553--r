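#' Simulator configuration
#'
#' Parameters of the stochastic mutation-accumulation simulator. Each
#' "generation" is one reverse-transcription (copying) cycle: every genome is
#' copied once, sites mutate independently during copying, and optionally the
#' copy switches template between two co-packaged genomes (copy-choice
#' recombination).
#'
#' @param mutation_rate Per-nucleotide per-cycle substitution probability
#'   (composition-weighted average over sites; see [mutation_spectrum()]).
#'   Canonical values: 1–3.4e-5 (literature estimates for HIV-1 reverse
#'   transcription) up to ~1e-4 (ongoing rate observed in iterated-vector
#'   evolution experiments).
#' @param generations Number of reverse-transcription cycles to simulate
#'   (non-negative). Under the labelling convention used throughout,
#'   generation label `F_k` corresponds to `k + 1` cycles: producing the
#'   parental vector stock is itself the first copying step.
#' @param population_size Number of genomes carried per generation.
#' @param spectrum A [mutation_spectrum()]; default is the G>A-dominated
#'   [default_spectrum()] (composition supplied at run time from the
#'   reference).
#' @param recombination_switch_rate Per-nucleotide probability of a template
#'   switch while copying a heterozygous virion.
#' @param heterozygous_virion_fraction Probability that a genome is
#'   co-packaged with a distinct, randomly chosen partner genome (a
#'   prerequisite for effective recombination under high-MOI transduction).
#' @param cis_lethal_mask Integer positions (1-based) where any substitution
#'   is lethal to the genome (lost cis-acting function); affected genomes
#'   are removed and replaced by resampling survivors.
#' @param seed Mandatory integer seed.
#'
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(mutation_rate = 1e-4,
                             generations = 17L,
                             population_size = 1000L,
                             spectrum = NULL,
                             recombination_switch_rate = 0,
                             heterozygous_virion_fraction = 0,
                             cis_lethal_mask = integer(0),
                             seed) {
  if (missing(seed)) stop("evolution_config() requires an explicit seed", call. = FALSE)
  stopifnot(
    mutation_rate >= 0, mutation_rate <= 1,
    generations >= 0,
    population_size >= 1,
    recombination_switch_rate >= 0, recombination_switch_rate <= 1,
    heterozygous_virion_fraction >= 0, heterozygous_virion_fraction <= 1
  )
  structure(
    list(
      mutation_rate = mutation_rate,
      generations = as.integer(generations),
      population_size = as.integer(population_size),
      spectrum = spectrum,
      recombination_switch_rate = recombination_switch_rate,
      heterozygous_virion_fraction = heterozygous_virion_fraction,
      cis_lethal_mask = as.integer(cis_lethal_mask),
      seed = as.integer(seed)
    ),
    class = "evolution_config"
  )
}

# F-number label for a genome that has been through `cycles` copying steps
generation_label_for_cycles <- function(cycles) {
  if (cycles == 0L) "plasmid" else paste0("F", cycles - 1L)
}

#' Simulate a directed-evolution library
#'
#' Carries `population_size` genomes through `generations` copying cycles.
#' During each cycle every site of every genome mutates independently with
#' probability `mutation_rate * rate_weight[current base]` (see
#' [mutation_spectrum()]); the substituted base is drawn from the spectrum's
#' conditional row. Optionally, a fraction of genomes is co-packaged with a
#' random partner and copied with template switching, and genomes carrying
#' any substitution inside `cis_lethal_mask` are removed and replaced by
#' resampled survivors. Fully deterministic given the configured seed.
#'
#' A clone's "mutated positions" are the positions at which its sequence
#' differs from the reference at observation time — a site that reverts to
#' the reference by back-mutation no longer counts, exactly as sequencing
#' would score it.
#'
#' @param config An [evolution_config()].
#' @param reference A [reference_gene()].
#'
#' @return An object of class `retro_library`: a list with
#'   \describe{
#'     \item{clones}{data frame: `clone_id`, `generation_label`, `n_mutations`.}
#'     \item{sequences}{named character vector of clone sequences.}
#'     \item{mutations}{mutation log: `clone_id`, `position`, `ref_base`,
#'       `alt_base`, `cycle_introduced` (cycle of the most recent event at
#'       that position).}
#'     \item{generations}{per-cycle summaries: `generation_label`,
#'       `cycle_count`, `mean_mutations_per_genome`, `genomes_surviving`.}
#'     \item{reference, config}{the inputs.}
#'   }
#' @export
#' @examples
#' ref <- random_reference(90, seed = 1)
#' cfg <- evolution_config(mutation_rate = 1e-3, generations = 5,
#'                         population_size = 50, seed = 42)
#' lib <- simulate_library(cfg, ref)
#' head(lib$clones)
simulate_library <- function(config, reference) {
  stopifnot(inherits(config, "evolution_config"), inherits(reference, "reference_gene"))
  n <- reference$length
  if (n == 0L) stop("zero-length reference rejected", call. = FALSE)
  mask <- config$cis_lethal_mask
  if (length(mask) && (any(mask < 1L) || any(mask > n))) {
    stop("cis_lethal_mask positions must lie within [1, reference length]", call. = FALSE)
  }
  spectrum <- config$spectrum
  if (is.null(spectrum)) spectrum <- default_spectrum(reference)
  pop <- config$population_size
  g <- config$generations
  ref_codes <- seq_to_int(reference$sequence)

  withr::with_seed(config$seed, {
    seqs <- matrix(rep(ref_codes, each = pop), nrow = pop, ncol = n)
    last_cycle <- matrix(0L, nrow = pop, ncol = n)
    gen_records <- vector("list", g)

    for (cyc in seq_len(g)) {
      # copy-choice recombination between co-packaged genomes
      if (config$heterozygous_virion_fraction > 0 && pop > 1L &&
          config$recombination_switch_rate > 0) {
        het <- which(runif(pop) < config$heterozygous_virion_fraction)
        for (i in het) {
          j <- sample.int(pop - 1L, 1L)
          if (j >= i) j <- j + 1L
          tmpl <- recombination_template(n, config$recombination_switch_rate)
          from_b <- tmpl == 2L
          if (any(from_b)) {
            seqs[i, from_b] <- seqs[j, from_b]
            last_cycle[i, from_b] <- last_cycle[j, from_b]
          }
        }
      }
      # substitution: per-site Bernoulli with base-dependent weight
      for (b in 1:4) {
        p_b <- min(config$mutation_rate * spectrum$rate_weight[b], 1)
        if (p_b <= 0) next
        idx <- which(seqs == b)
        if (!length(idx)) next
        k <- rbinom(1L, length(idx), p_b)
        if (k == 0L) next
        hit <- idx[sample.int(length(idx), k)]
        seqs[hit] <- sample.int(4L, k, replace = TRUE, prob = spectrum$conditional[b, ])
        last_cycle[hit] <- cyc
      }
      # cis-lethal mask: purge and resample
      if (length(mask)) {
        dead <- rowSums(seqs[, mask, drop = FALSE] !=
                          rep(ref_codes[mask], each = pop)) > 0L
        n_surv <- sum(!dead)
        if (n_surv == 0L) {
          stop(sprintf(
            "extinction: all %d genomes removed by the cis-lethal mask at cycle %d (generation %s)",
            pop, cyc, generation_label_for_cycles(cyc)
          ), call. = FALSE)
        }
        if (any(dead)) {
          donors <- which(!dead)[sample.int(n_surv, sum(dead), replace = TRUE)]
          seqs[dead, ] <- seqs[donors, , drop = FALSE]
          last_cycle[dead, ] <- last_cycle[donors, , drop = FALSE]
        }
      } else {
        n_surv <- pop
      }
      diff_now <- seqs != rep(ref_codes, each = pop)
      gen_records[[cyc]] <- data.frame(
        generation_label = generation_label_for_cycles(cyc),
        cycle_count = cyc,
        mean_mutations_per_genome = mean(rowSums(diff_now)),
        genomes_surviving = n_surv,
        stringsAsFactors = FALSE
      )
    }

    label <- generation_label_for_cycles(g)
    clone_id <- sprintf("%s_clone%04d", label, seq_len(pop))
    diff_mat <- seqs != rep(ref_codes, each = pop)
    n_mut <- rowSums(diff_mat)
    hits <- which(diff_mat, arr.ind = TRUE)
    ord <- order(hits[, 1L], hits[, 2L])
    hits <- hits[ord, , drop = FALSE]
    mutations <- data.frame(
      clone_id = clone_id[hits[, 1L]],
      position = unname(hits[, 2L]),
      ref_base = DNA_BASES[ref_codes[hits[, 2L]]],
      alt_base = DNA_BASES[seqs[hits]],
      cycle_introduced = last_cycle[hits],
      stringsAsFactors = FALSE
    )
    sequences <- apply(matrix(DNA_BASES[seqs], nrow = pop), 1L, paste, collapse = "")
    names(sequences) <- clone_id

    structure(
      list(
        clones = data.frame(
          clone_id = clone_id,
          generation_label = label,
          n_mutations = n_mut,
          stringsAsFactors = FALSE
        ),
        sequences = sequences,
        mutations = mutations,
        generations = do.call(rbind, gen_records),
        reference = reference,
        config = config
      ),
      class = "retro_library"
    )
  })
}

#' @export
print.retro_library <- function(x, ...) {
  cat(sprintf(
    "<retro_library> %d clones at %s (%d cycles), reference %s (%d nt)\n",
    nrow(x$clones), x$clones$generation_label[1L], x$config$generations,
    x$reference$name, x$reference$length
  ))
  cat(sprintf(
    "  mean mutated positions per clone: %.3f (total events logged: %d)\n",
    mean(x$clones$n_mutations), nrow(x$mutations)
  ))
  invisible(x)
}

# template path for copy-choice recombination: vector of 1/2 per position
recombination_template <- function(n, switch_rate) {
  start <- sample.int(2L, 1L)
  if (n == 1L) return(start)
  switches <- runif(n - 1L) < switch_rate
  1L + (cumsum(c(start - 1L, switches)) %% 2L)
}

#' Copy-choice recombination between two parent sequences
#'
#' Models template switching during reverse transcription of a heterozygous
#' virion: copying starts on a uniformly chosen parent and switches template
#' at each subsequent position independently with probability `switch_rate`.
#' Every offspring position equals the corresponding position of the parent
#' being copied at that moment.
#'
#' @param parent_a,parent_b Equal-length sequence strings.
#' @param switch_rate Per-nucleotide template-switch probability.
#' @param seed Mandatory integer seed.
#' @return The offspring sequence string.
#' @export
simulate_recombination <- function(parent_a, parent_b, switch_rate, seed) {
  if (missing(seed)) stop("simulate_recombination() requires an explicit seed", call. = FALSE)
  stopifnot(is.character(parent_a), is.character(parent_b),
            switch_rate >= 0, switch_rate <= 1)
  if (nchar(parent_a) != nchar(parent_b)) {
    stop("parents must have equal length", call. = FALSE)
  }
  n <- nchar(parent_a)
  a <- strsplit(parent_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(parent_b, "", fixed = TRUE)[[1L]]
  withr::with_seed(as.integer(seed), {
    tmpl <- recombination_template(n, switch_rate)
    out <- a
    out[tmpl == 2L] <- b[tmpl == 2L]
    paste(out, collapse = "")
  })
}
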