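#' Substitution spectrum
#'
#' A mutation spectrum describes the relative frequencies of the 12 ordered
#' base substitutions (e.g. `G>A`). It is stored in two linked forms:
#'
#' * `joint` — a 4x4 matrix (rows = current base, columns = substituted
#'   base, diagonal zero) giving the probability that a substitution event,
#'   drawn at random from the process, is of each ordered type. Entries sum
#'   to 1 over the 12 off-diagonal cells.
#' * `conditional` — the same matrix with each row renormalized to sum to 1:
#'   the distribution of the substituted base given that a mutation occurs
#'   at a site of a given current base.
#'
#' Because substitution types are not equally available at every site (a
#' G>A event can only occur at a G), realizing a target joint spectrum on a
#' concrete sequence requires per-base site weights: a site whose current
#' base is `b` mutates with probability `mutation_rate * rate_weight[b]`,
#' where `rate_weight[b] = rowsum(joint)[b] / composition[b]`. The
#' composition-weighted mean of `rate_weight` is exactly 1, so the average
#' per-nucleotide per-cycle rate over the gene equals `mutation_rate`, while
#' the realized event-type frequencies converge to `joint`. This is the
#' standard picture of reverse-transcriptase G>A hypermutation: G sites are
#' hit more often, not merely resolved differently once hit.
#'
#' @param joint 4x4 numeric matrix with dimnames `A,C,G,T`, zero diagonal,
#'   non-negative entries summing to 1 (within 1e-9).
#' @param composition Named base frequencies of the sequence the spectrum
#'   will act on (see [base_composition()]); used to derive site weights.
#'
#' @return An object of class `mutation_spectrum` with fields `joint`,
#'   `conditional`, `rate_weight` and `composition`.
#' @seealso [default_spectrum()], [uniform_spectrum()], [sample_substitutions()]
#' @export
mutation_spectrum <- function(joint, composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(is.matrix(joint), all(dim(joint) == c(4L, 4L)))
  if (is.null(dimnames(joint))) dimnames(joint) <- list(DNA_BASES, DNA_BASES)
  joint <- joint[DNA_BASES, DNA_BASES]
  if (any(joint < 0)) stop("spectrum entries must be non-negative", call. = FALSE)
  if (any(diag(joint) != 0)) stop("self-substitutions are excluded: diagonal must be 0", call. = FALSE)
  if (abs(sum(joint) - 1) > 1e-9) stop("joint spectrum must sum to 1", call. = FALSE)
  composition <- composition[DNA_BASES]
  stopifnot(abs(sum(composition) - 1) < 1e-6)
  row_mass <- rowSums(joint)
  if (any(row_mass > 0 & composition == 0)) {
    stop("spectrum places mass on a base absent from the composition", call. = FALSE)
  }
  conditional <- joint
  nz <- row_mass > 0
  conditional[nz, ] <- joint[nz, , drop = FALSE] / row_mass[nz]
  rate_weight <- ifelse(composition > 0, row_mass / composition, 0)
  names(rate_weight) <- DNA_BASES
  structure(
    list(
      joint = joint, conditional = conditional,
      rate_weight = rate_weight, composition = composition
    ),
    class = "mutation_spectrum"
  )
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("<mutation_spectrum> joint type probabilities (row = from, col = to):\n")
  print(round(x$joint, 4))
  cat("site rate weights:", paste(sprintf("%s=%.3f", DNA_BASES, x$rate_weight), collapse = " "), "\n")
  invisible(x)
}

#' Default G>A-dominated substitution spectrum
#'
#' The default spectrum used by the simulator: the `G>A` transition carries
#' a configurable share of the total substitution mass (default 62.3%, the
#' dominant error class of HIV-1 reverse transcriptase) and the remaining 11
#' substitution types share the rest uniformly.
#'
#' @param reference Optional [reference_gene()] (or sequence string); when
#'   given, its base composition is used for the site weights so that the
#'   realized event fractions match the configured mass on that sequence.
#' @param g_to_a Total substitution mass on the G>A transition, in `[0, 1)`.
#' @return A [mutation_spectrum()].
#' @export
default_spectrum <- function(reference = NULL, g_to_a = 0.623) {
  stopifnot(g_to_a >= 0, g_to_a < 1)
  joint <- matrix((1 - g_to_a) / 11, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  diag(joint) <- 0
  joint["G", "A"] <- g_to_a
  comp <- if (is.null(reference)) {
    c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  } else if (inherits(reference, "reference_gene")) {
    base_composition(reference$sequence)
  } else {
    base_composition(reference)
  }
  mutation_spectrum(joint, comp)
}

#' Uniform substitution spectrum
#'
#' All 12 ordered substitutions equally likely; with a uniform composition
#' every site mutates at the same rate, making the process positionally
#' uniform by construction.
#'
#' @inheritParams default_spectrum
#' @return A [mutation_spectrum()].
#' @export
uniform_spectrum <- function(reference = NULL) {
  default_spectrum(reference, g_to_a = 1 / 12)
}

#' Sample substitution events from a spectrum on a reference
#'
#' Draws `n` independent substitution events on the reference sequence under
#' the spectrum's site-weighted model: positions are drawn with probability
#' proportional to the rate weight of their reference base, and the
#' substituted base from the conditional row. The realized type frequencies
#' converge to the spectrum's joint probabilities.
#'
#' @param spectrum A [mutation_spectrum()].
#' @param reference A [reference_gene()].
#' @param n Number of events to draw.
#' @param seed Mandatory integer seed.
#' @return A data frame of mutation events (`position`, `ref_base`,
#'   `alt_base`), one row per event (positions may repeat).
#' @export
sample_substitutions <- function(spectrum, reference, n, seed) {
  stopifnot(inherits(spectrum, "mutation_spectrum"), inherits(reference, "reference_gene"))
  if (missing(seed)) stop("sample_substitutions() requires an explicit seed", call. = FALSE)
  codes <- seq_to_int(reference$sequence)
  w <- spectrum$rate_weight[codes]
  withr::with_seed(as.integer(seed), {
    pos <- sample.int(reference$length, n, replace = TRUE, prob = w)
    ref_code <- codes[pos]
    alt_code <- integer(n)
    for (b in 1:4) {
      sel <- ref_code == b
      if (any(sel)) {
        alt_code[sel] <- sample.int(4L, sum(sel), replace = TRUE, prob = spectrum$conditional[b, ])
      }
    }
    data.frame(
      position = pos,
      ref_base = DNA_BASES[ref_code],
      alt_base = DNA_BASES[alt_code],
      stringsAsFactors = FALSE
    )
  })
}
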