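#' Replication cycles required for a target library complexity
#'
#' Linear planning formula: to accumulate `p` mutations per copy of a target
#' gene of `n` nt under a per-nucleotide per-cycle rate `m`, the number of
#' copying cycles required is `p / (m * n)`.
#'
#' @param p Desired mutations per target-gene copy (> 0).
#' @param m Mutation rate per nt per cycle (> 0).
#' @param n Target gene length in nt (>= 1).
#' @return List with `cycles` (real-valued) and `cycles_ceiling` (integer
#'   recommendation).
#' @export
#' @examples
#' cycles_required(p = 1, m = 1e-4, n = 783)
cycles_required <- function(p, m, n) {
  stopifnot(p > 0, n >= 1)
  if (m * n == 0) stop("m * n must be positive", call. = FALSE)
  cycles <- p / (m * n)
  list(cycles = cycles, cycles_ceiling = as.integer(ceiling(cycles)))
}

#' Expected mutations per gene copy after a number of cycles
#'
#' Linear expectation `m * n * cycles`, together with the exact
#' binomial-complement expectation `n * (1 - (1 - m)^cycles)` for
#' cross-checking: the linear form slightly overestimates once `m * cycles`
#' is no longer small, because a site can only be counted mutated once.
#'
#' @param m Mutation rate per nt per cycle.
#' @param n Gene length (nt).
#' @param cycles Number of copying cycles.
#' @return List with `linear` and `exact`.
#' @export
expected_mutations <- function(m, n, cycles) {
  stopifnot(m >= 0, n >= 0, cycles >= 0)
  list(
    linear = m * n * cycles,
    exact = n * (1 - (1 - m)^cycles)
  )
}

#' Poisson multiplicity-of-infection statistics
#'
#' Models proviral copies per cell as Poisson with mean `moi` (standard for
#' single-hit VSV-G pseudotyped transduction). Reports the probability that
#' a cell is transduced at all, and the probability that a transduced cell
#' carries more than one provirus — the quantity a screening design drives
#' down by choosing a low MOI so each cell reports on a single variant,
#' while the evolution phase drives it up (high MOI) to favour heterozygous
#' virions and recombination.
#'
#' @param moi Mean vector copies per cell (Poisson mean, >= 0).
#' @return List of class `transduction_stats` with `moi`, `p_transduced`
#'   (`1 - exp(-moi)`) and `p_multi_given_transduced`
#'   (`P(N >= 2 | N >= 1)`); both 0 at `moi = 0` by continuity.
#' @export
#' @examples
#' multiplicity_stats(0.03)
multiplicity_stats <- function(moi) {
  if (moi < 0) stop("MOI must be non-negative", call. = FALSE)
  if (moi == 0) {
    p_trans <- 0
    p_multi <- 0
  } else {
    p_trans <- ppois(0, moi, lower.tail = FALSE)           # 1 - e^-moi
    p_multi <- ppois(1, moi, lower.tail = FALSE) / p_trans # P(>=2)/P(>=1)
  }
  structure(
    list(moi = moi, p_transduced = p_trans, p_multi_given_transduced = p_multi),
    class = "transduction_stats"
  )
}

#' @export
print.transduction_stats <- function(x, ...) {
  cat(sprintf(
    "<transduction_stats> MOI=%.4g: P(transduced)=%.4g, P(>1 provirus | transduced)=%.4g\n",
    x$moi, x$p_transduced, x$p_multi_given_transduced
  ))
  invisible(x)
}

#' Largest MOI meeting a multi-provirus tolerance
#'
#' Inverts [multiplicity_stats()]: finds the largest Poisson mean such that
#' the fraction of transduced cells carrying more than one provirus does not
#' exceed `max_multi_fraction`. `P(N >= 2 | N >= 1)` is strictly increasing
#' in the mean, so the bound is found by monotone root-finding (relative
#' tolerance 1e-6).
#'
#' @param max_multi_fraction Tolerated fraction of multiply-transduced cells
#'   among transduced cells, in (0, 1).
#' @return The recommended MOI (Poisson mean).
#' @export
#' @examples
#' recommend_moi(0.015) # ~0.03, the classic low-MOI screening regime
recommend_moi <- function(max_multi_fraction) {
  stopifnot(max_multi_fraction > 0, max_multi_fraction < 1)
  f <- function(l) multiplicity_stats(l)$p_multi_given_transduced - max_multi_fraction
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, interval = c(1e-12, upper), tol = .Machine$double.eps^0.5)$root
}

#' Cycles-versus-gene-size planning curve
#'
#' Evaluates [cycles_required()] over a range of target-gene sizes for one
#' or more mutation rates — the planning curve relating target size to the
#' number of copying cycles needed for one mutation per gene copy.
#'
#' @param m Numeric vector of mutation rates per nt per cycle.
#' @param n_range Integer vector of gene sizes (nt).
#' @param p Desired mutations per gene copy (default 1).
#' @return Data frame with columns `m`, `n`, `cycles`.
#' @export
cycles_curve <- function(m, n_range, p = 1) {
  grid <- expand.grid(n = n_range, m = m)
  grid$cycles <- p / (grid$m * grid$n)
  grid[, c("m", "n", "cycles")]
}

#' Plot planning curves
#'
#' Base-graphics rendering of [cycles_curve()]: cycles needed for one
#' mutation per gene copy versus target size, one line per rate (lower
#' rates give higher curves).
#'
#' @inheritParams cycles_curve
#' @param ... Passed to [graphics::matplot()].
#' @return The curve data, invisibly.
#' @export
plot_cycles_curves <- function(m, n_range = seq(200L, 3000L, by = 50L), p = 1, ...) {
  dat <- cycles_curve(m, n_range, p)
  mat <- sapply(m, function(mm) dat$cycles[dat$m == mm])
  graphics::matplot(
    n_range, mat, type = "l", lty = seq_along(m), col = "black",
    xlab = "target gene size (nt)", ylab = "cycles for one mutation per copy", ...
  )
  graphics::legend("topright", legend = sprintf("m = %.2g", m),
                   lty = seq_along(m), bty = "n")
  invisible(dat)
}
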