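#' Viability-plate generator parameters
#'
#' Parameters of the synthetic 96-well viability assay (MTT/OD570-style
#' readout) used to emulate prodrug-sensitivity screens. Each clone's
#' viability follows a log-logistic dose-response
#' `v(c) = 1 / (1 + (c / IC50)^hill)`; the well readout is
#' `baseline_signal * v(c)` plus Gaussian noise, truncated at 0.
#'
#' Defaults describe the HEK-293T screening scenario: untransduced cells are
#' already sensitive near the screening concentration through their
#' endogenous kinase (IC50 14 nM), a wild-type transgene adds a modest extra
#' sensitization (IC50 12 nM), library clones without a sensitizing variant
#' behave like untransduced cells, and sensitizer clones have the baseline
#' IC50 divided by `sensitizer_fold`.
#'
#' @param baseline_ic50_nM IC50 of non-sensitizer clones, nM.
#' @param hill Hill slope of the dose-response.
#' @param baseline_signal Readout at concentration 0 (arbitrary OD units).
#' @param noise_sd Gaussian readout noise standard deviation (same units).
#' @param sensitizer_ids Clone ids designated as sensitizers.
#' @param sensitizer_fold IC50 fold-reduction of sensitizer clones.
#' @param clone_ic50_nM Optional named numeric vector of per-clone IC50
#'   overrides (e.g. control populations), taking precedence over the rules
#'   above.
#' @return A list of class `plate_params`.
#' @export
plate_params <- function(baseline_ic50_nM = 14,
                         hill = 2,
                         baseline_signal = 1,
                         noise_sd = 0.01,
                         sensitizer_ids = character(0),
                         sensitizer_fold = 60,
                         clone_ic50_nM = NULL) {
  stopifnot(baseline_ic50_nM > 0, hill > 0, baseline_signal > 0,
            noise_sd >= 0, sensitizer_fold > 0)
  structure(
    list(
      baseline_ic50_nM = baseline_ic50_nM, hill = hill,
      baseline_signal = baseline_signal, noise_sd = noise_sd,
      sensitizer_ids = sensitizer_ids, sensitizer_fold = sensitizer_fold,
      clone_ic50_nM = clone_ic50_nM
    ),
    class = "plate_params"
  )
}

# log-logistic viability with v(0) = 1
logistic_viability <- function(conc, ic50, hill) {
  1 / (1 + (conc / ic50)^hill)
}

#' Generate a synthetic viability plate
#'
#' Produces clone x concentration x experiment readouts for a prodrug
#' sensitivity screen, with designated sensitizer clones shifted to a lower
#' IC50. The implanted sensitizer ids are recorded as an attribute
#' (`implanted_sensitizers`) so that downstream hit calling can be validated
#' against the generator's own log.
#'
#' @param clones Character vector of clone ids, or a `retro_library` (its
#'   clone ids are used).
#' @param concentrations Numeric prodrug concentrations in nM; must be
#'   non-negative and include 0 (death rates are normalized to the
#'   0-concentration well).
#' @param params A [plate_params()].
#' @param n_experiments Number of independent replicate experiments.
#' @param seed Mandatory integer seed.
#' @return A data frame of class `viability_plate` with columns `clone_id`,
#'   `experiment_id`, `concentration_nM`, `readout`, plus attributes
#'   `implanted_sensitizers`, `clone_ic50_nM` and `params`.
#' @export
generate_viability_plate <- function(clones, concentrations, params = plate_params(),
                                     n_experiments = 3L, seed) {
  if (missing(seed)) stop("generate_viability_plate() requires an explicit seed", call. = FALSE)
  if (inherits(clones, "retro_library")) clones <- clones$clones$clone_id
  stopifnot(is.character(clones), length(clones) >= 1L,
            inherits(params, "plate_params"), n_experiments >= 1L)
  if (any(concentrations < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (!any(concentrations == 0)) {
    stop("concentration grid must include 0 (required to normalize death rates)", call. = FALSE)
  }
  ic50 <- rep(params$baseline_ic50_nM, length(clones))
  names(ic50) <- clones
  ic50[clones %in% params$sensitizer_ids] <-
    params$baseline_ic50_nM / params$sensitizer_fold
  if (!is.null(params$clone_ic50_nM)) {
    ovr <- params$clone_ic50_nM
    unknown <- setdiff(names(ovr), clones)
    if (length(unknown)) {
      stop("clone_ic50_nM overrides name unknown clones: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    ic50[names(ovr)] <- ovr
  }
  grid <- expand.grid(
    concentration_nM = concentrations,
    clone_id = clones,
    experiment_id = paste0("exp", seq_len(n_experiments)),
    stringsAsFactors = FALSE
  )[, c("clone_id", "experiment_id", "concentration_nM")]
  withr::with_seed(as.integer(seed), {
    v <- logistic_viability(grid$concentration_nM, ic50[grid$clone_id], params$hill)
    readout <- params$baseline_signal * v
    if (params$noise_sd > 0) readout <- readout + rnorm(nrow(grid), sd = params$noise_sd)
    grid$readout <- pmax(readout, 0)
  })
  structure(
    grid,
    implanted_sensitizers = intersect(clones, params$sensitizer_ids),
    clone_ic50_nM = ic50,
    params = params,
    class = c("viability_plate", "data.frame")
  )
}

# schema check shared by the generator output and files read from disk
validate_plate <- function(plate) {
  required <- c("clone_id", "experiment_id", "concentration_nM", "readout")
  missing_cols <- setdiff(required, names(plate))
  if (length(missing_cols)) {
    stop("plate is missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(plate$readout < 0)) stop("plate readouts must be non-negative", call. = FALSE)
  has_zero <- tapply(plate$concentration_nM, paste(plate$clone_id, plate$experiment_id),
                     function(cc) any(cc == 0))
  if (!all(has_zero)) {
    bad <- names(has_zero)[!has_zero]
    stop("0-concentration well missing for: ", paste(head(bad, 5L), collapse = "; "),
         call. = FALSE)
  }
  invisible(plate)
}
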