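#' Cell death rate from viability readouts
#'
#' `1 - readout_at_conc / readout_at_zero`, clamped to `[0, 1]`. The
#' convention is explicit: the *living* fraction is the OD ratio between the
#' treated and untreated wells, and death is its complement. Values outside
#' `[0, 1]` before clamping (readout noise can push the ratio above 1) are
#' counted in the `clamped` attribute.
#'
#' @param readout_at_conc Readout(s) at the test concentration.
#' @param readout_at_zero Matching readout(s) at concentration 0 (must be
#'   strictly positive).
#' @return Numeric vector of death rates in `[0, 1]`, with attribute
#'   `clamped` giving the number of clamped values.
#' @export
death_rate <- function(readout_at_conc, readout_at_zero) {
  if (any(readout_at_zero <= 0)) {
    stop("readout at concentration 0 must be strictly positive", call. = FALSE)
  }
  if (any(readout_at_conc < 0)) stop("readouts must be non-negative", call. = FALSE)
  raw <- 1 - readout_at_conc / readout_at_zero
  clamped <- sum(raw < 0 | raw > 1)
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clamped") <- clamped
  out
}

# mean readout per (clone, experiment) at a given concentration
plate_readout <- function(plate, conc) {
  sel <- plate$concentration_nM == conc
  tapply(plate$readout[sel], list(plate$clone_id[sel], plate$experiment_id[sel]),
         mean)
}

#' Replicate-wise hit calling against two control populations
#'
#' For every clone and experiment, computes the death rate at the screening
#' concentration and counts the experiments in which the clone's death rate
#' strictly exceeds the death rates of *both* control populations. A clone
#' is a hit when this count reaches `min_experiments` (default 1: a single
#' exceedance across the replicate experiments suffices).
#'
#' @param plate A viability plate (data frame with `clone_id`,
#'   `experiment_id`, `concentration_nM`, `readout`); every
#'   (clone, experiment) must include a 0-concentration well.
#' @param clone_ids Clones to score.
#' @param control_ids Exactly two control ids (e.g. untransduced cells and
#'   cells carrying the wild-type transgene), present in every experiment.
#' @param screening_conc Concentration (nM) at which the screen is read
#'   (default 10).
#' @param min_experiments Minimum exceedance count for a hit (default 1).
#' @return Data frame of class `screen_result` with `clone_id`, `n_exceed`,
#'   `hit`, plus a `death_rates` attribute (clone x experiment matrix
#'   including the controls).
#' @export
call_hits <- function(plate, clone_ids, control_ids, screening_conc = 10,
                      min_experiments = 1L) {
  validate_plate(plate)
  if (length(control_ids) != 2L) {
    stop("exactly two control populations are required", call. = FALSE)
  }
  if (!screening_conc %in% plate$concentration_nM) {
    stop("screening concentration ", screening_conc, " nM absent from the plate",
         call. = FALSE)
  }
  at_zero <- plate_readout(plate, 0)
  at_conc <- plate_readout(plate, screening_conc)
  experiments <- colnames(at_conc)
  all_ids <- c(clone_ids, control_ids)
  missing_ids <- all_ids[!all_ids %in% rownames(at_conc)]
  if (length(missing_ids)) {
    stop("clone(s) absent from the plate: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(at_conc[control_ids, ])) || any(is.na(at_zero[control_ids, ]))) {
    stop("a control population is missing from at least one experiment", call. = FALSE)
  }
  dr <- matrix(NA_real_, length(all_ids), length(experiments),
               dimnames = list(all_ids, experiments))
  for (ex in experiments) {
    dr[, ex] <- death_rate(at_conc[all_ids, ex], at_zero[all_ids, ex])
  }
  control_max <- apply(dr[control_ids, , drop = FALSE], 2L, max)
  exceed <- sweep(dr[clone_ids, , drop = FALSE], 2L, control_max, `>`)
  n_exceed <- rowSums(exceed, na.rm = TRUE)
  res <- data.frame(
    clone_id = clone_ids,
    n_exceed = as.integer(n_exceed[clone_ids]),
    hit = unname(n_exceed[clone_ids] >= min_experiments),
    stringsAsFactors = FALSE
  )
  attr(res, "death_rates") <- dr
  attr(res, "screening_conc") <- screening_conc
  class(res) <- c("screen_result", "data.frame")
  res
}

# 4-parameter log-logistic viability model
ll4 <- function(conc, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of
#' `v(c) = bottom + (top - bottom) / (1 + (c / IC50)^hill)`
#' to viability fractions, by Levenberg-Marquardt with box constraints
#' (`hill > 0`, `ic50 > 0`) and a multi-start grid over IC50 (log-spaced
#' across the positive concentrations) and hill slope. The reported `ic50`
#' is the inflection concentration of the fitted curve (relative IC50); the
#' concentration at which the fitted viability crosses 0.5 is reported
#' separately as `ic50_abs` (`NA` when the curve never crosses 0.5).
#'
#' Degenerate inputs — viability essentially flat across the grid — are
#' flagged `converged = FALSE` with `ic50 = NA` rather than returning an
#' arbitrary curve.
#'
#' @param concentrations Concentrations in nM (>= 4 distinct values,
#'   including 0).
#' @param viability Viability fractions in `[0, 1.5]` (MTT ratios can
#'   slightly exceed 1), same length.
#' @return An object of class `dose_response_fit`: list with `ic50`,
#'   `hill`, `top`, `bottom`, `rss`, `converged`, `ic50_abs`, and the data
#'   and fitted values (used for residual bootstraps).
#' @export
#' @examples
#' conc <- c(0, 5, 15, 40, 110, 300, 800, 2200)
#' v <- 1 / (1 + (conc / 75)^1.5)
#' fit_dose_response(conc, v)$ic50
fit_dose_response <- function(concentrations, viability) {
  stopifnot(length(concentrations) == length(viability))
  if (length(unique(concentrations)) < 4L) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  if (!any(concentrations == 0)) {
    stop("the concentration grid must include 0", call. = FALSE)
  }
  if (any(concentrations < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (any(viability < 0 | viability > 1.5)) {
    stop("viability outside [0, 1.5]: treat as a plate error upstream", call. = FALSE)
  }
  dat <- data.frame(conc = concentrations, v = viability)
  flat <- diff(range(viability)) < 0.05
  if (flat) {
    return(structure(
      list(ic50 = NA_real_, hill = NA_real_, top = mean(viability),
           bottom = mean(viability), rss = NA_real_, converged = FALSE,
           ic50_abs = NA_real_, data = dat, fitted = rep(mean(viability), nrow(dat))),
      class = "dose_response_fit"
    ))
  }
  pos <- sort(unique(concentrations[concentrations > 0]))
  ic50_starts <- exp(seq(log(min(pos)), log(max(pos)), length.out = 5L))
  hill_starts <- c(0.5, 1, 2, 4)
  top0 <- max(viability)
  bottom0 <- min(viability)
  best <- NULL
  for (i0 in ic50_starts) {
    for (h0 in hill_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          v ~ ll4(conc, bottom, top, ic50, hill),
          data = dat,
          start = list(bottom = bottom0, top = top0, ic50 = i0, hill = h0),
          lower = c(bottom = -0.25, top = 0, ic50 = min(pos) * 1e-4, hill = 0.01),
          upper = c(bottom = 1.5, top = 2, ic50 = max(pos) * 1e4, hill = 20),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(ic50 = NA_real_, hill = NA_real_, top = NA_real_, bottom = NA_real_,
           rss = NA_real_, converged = FALSE, ic50_abs = NA_real_,
           data = dat, fitted = rep(NA_real_, nrow(dat))),
      class = "dose_response_fit"
    ))
  }
  cf <- coef(best$fit)
  # honest convergence: a sigmoid with a real amplitude, inflection inside
  # a generous window around the measured range
  converged <- is.finite(cf[["ic50"]]) &&
    (cf[["top"]] - cf[["bottom"]]) > 0.05 &&
    cf[["ic50"]] > min(pos) * 1e-3 && cf[["ic50"]] < max(pos) * 1e3
  ic50_abs <- NA_real_
  if (converged && cf[["top"]] > 0.5 && cf[["bottom"]] < 0.5) {
    # solve bottom + (top-bottom)/(1+(c/ic50)^hill) = 0.5
    r <- (cf[["top"]] - 0.5) / (0.5 - cf[["bottom"]])
    ic50_abs <- cf[["ic50"]] * r^(1 / cf[["hill"]])
  }
  structure(
    list(
      ic50 = unname(cf[["ic50"]]), hill = unname(cf[["hill"]]),
      top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
      rss = best$rss, converged = converged, ic50_abs = ic50_abs,
      data = dat, fitted = unname(fitted(best$fit))
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<dose_response_fit> NOT converged (flat or degenerate response)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<dose_response_fit> IC50 = %.4g nM (hill %.3g, top %.3g, bottom %.3g, rss %.3g)\n",
    x$ic50, x$hill, x$top, x$bottom, x$rss
  ))
  if (!is.na(x$ic50_abs)) cat(sprintf("  50%%-viability crossing: %.4g nM\n", x$ic50_abs))
  invisible(x)
}

#' IC50 fold-change between two fitted dose-response curves
#'
#' `ic50_reference / ic50_test` (so a sensitizing variant yields a fold
#' > 1), with a seeded percentile bootstrap interval obtained by resampling
#' each fit's residuals, re-adding them to the fitted curves and refitting.
#'
#' @param fit_reference,fit_test Converged [fit_dose_response()] objects.
#' @param n_boot Number of bootstrap replicates (default 199).
#' @param seed Mandatory integer seed.
#' @param conf Interval level (default 0.95).
#' @return List with `fold`, `ci_low`, `ci_high`, `n_boot_ok`.
#' @export
fold_change <- function(fit_reference, fit_test, n_boot = 199L, seed, conf = 0.95) {
  if (missing(seed)) stop("fold_change() requires an explicit seed", call. = FALSE)
  stopifnot(inherits(fit_reference, "dose_response_fit"),
            inherits(fit_test, "dose_response_fit"))
  if (!fit_reference$converged || !fit_test$converged) {
    stop("fold_change() requires two converged fits", call. = FALSE)
  }
  fold <- fit_reference$ic50 / fit_test$ic50
  boot_one <- function(fit) {
    res <- fit$data$v - fit$fitted
    v_star <- fit$fitted + sample(res, length(res), replace = TRUE)
    v_star <- pmin(pmax(v_star, 0), 1.5)
    bf <- fit_dose_response(fit$data$conc, v_star)
    if (bf$converged) bf$ic50 else NA_real_
  }
  ratios <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) boot_one(fit_reference) / boot_one(fit_test),
           numeric(1L))
  })
  ratios <- ratios[is.finite(ratios)]
  alpha <- 1 - conf
  ci <- if (length(ratios) >= 10L) {
    unname(quantile(ratios, c(alpha / 2, 1 - alpha / 2)))
  } else {
    c(NA_real_, NA_real_)
  }
  list(fold = fold, ci_low = ci[1L], ci_high = ci[2L], n_boot_ok = length(ratios))
}

#' Welch two-sample comparison of viability at one concentration
#'
#' Welch (unequal-variance) two-sample t-test of viability fractions between
#' two populations at a single prodrug concentration; Welch is the default
#' because it reduces to the classical test under equal variances and is
#' robust otherwise. Degenerate inputs (zero variance in both groups) are
#' resolved by convention: equal means give `p = 1`, unequal means `p = 0`
#' (the groups are exactly separated), both flagged `degenerate`.
#'
#' @param group_a,group_b Numeric vectors of viability fractions (each of
#'   length >= 2).
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
compare_populations <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    equal <- mean(group_a) == mean(group_b)
    message("compare_populations: zero variance in both groups; p set by convention")
    return(list(
      t = if (equal) 0 else sign(mean(group_a) - mean(group_b)) * Inf,
      df = NA_real_,
      p_value = if (equal) 1 else 0,
      mean_a = mean(group_a), mean_b = mean(group_b),
      degenerate = TRUE
    ))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(group_a), mean_b = mean(group_b),
    degenerate = FALSE
  )
}

#' Per-clone screening summary table
#'
#' Combines hit calling with (optional) per-clone dose-response fits into
#' the screen's result table.
#'
#' @inheritParams call_hits
#' @param fit_ic50 When `TRUE`, fit a dose-response per clone (pooling
#'   experiments) and report the IC50 and fold versus the second control
#'   (the wild-type-transgene population).
#' @return Data frame with `clone_id`, `n_exceed`, `hit` and, when
#'   requested, `ic50_nM` and `fold_vs_reference`.
#' @export
screen_table <- function(plate, clone_ids, control_ids, screening_conc = 10,
                         min_experiments = 1L, fit_ic50 = FALSE) {
  res <- call_hits(plate, clone_ids, control_ids, screening_conc, min_experiments)
  out <- as.data.frame(res)
  if (fit_ic50) {
    viab_curve <- function(id) {
      sel <- plate$clone_id == id
      zero <- plate_readout(plate, 0)[id, ]
      v <- plate$readout[sel] / zero[plate$experiment_id[sel]]
      fit_dose_response(plate$concentration_nM[sel], pmin(pmax(v, 0), 1.5))
    }
    ref_fit <- viab_curve(control_ids[2L])
    fits <- lapply(clone_ids, viab_curve)
    out$ic50_nM <- vapply(fits, function(f) f$ic50, numeric(1L))
    out$fold_vs_reference <- if (ref_fit$converged) ref_fit$ic50 / out$ic50_nM else NA_real_
  }
  out
}
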