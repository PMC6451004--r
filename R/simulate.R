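#' Experimental design specification for simulated feeding trials
#'
#' Defaults reproduce the standard vial design this package targets: 11 prey
#' densities from 5 to 300, six replicate predator vials and six replicate
#' predator-free control vials per density, a 4-hour exposure, and four
#' treatments crossing two prey size classes with substrate absent/present —
#' 528 vials in all.
#'
#' Time is measured in days throughout (rates per day, handling times in
#' days), the unit in which the canonical parameter magnitudes of
#' [fr_default_truth()] reproduce realistic consumption levels; the default
#' exposure is therefore `1/6` (4 hours).
#'
#' @param densities Strictly increasing positive prey densities.
#' @param replicates Replicate vials per condition (>= 1).
#' @param exposure_time Exposure duration in days (> 0; default `1/6`, a
#'   4-hour trial).
#' @param treatments Tibble with columns `prey_size`, `substrate`.
#' @param include_controls Whether to generate predator-free control vials.
#' @param control_recovery Per-prey recovery probability in control vials,
#'   in (0, 1]; 1 means controls count exactly the nominal density. Values
#'   below 1 emulate counting losses, which can push predator-vial counts
#'   above the control mean and exercise the zero-clamp.
#' @return A list of class `fr_design` echoing the (validated) arguments.
#' @export
fr_design <- function(densities = c(5, 10, 15, 20, 30, 50, 75, 100, 150, 200, 300),
                      replicates = 6, exposure_time = 1 / 6,
                      treatments = tidyr::expand_grid(
                        prey_size = c("small", "large"),
                        substrate = c("absent", "present")),
                      include_controls = TRUE, control_recovery = 1) {
  if (any(densities <= 0) || is.unsorted(densities, strictly = TRUE)) {
    abort("`densities` must be positive and strictly increasing.")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (exposure_time <= 0) abort("`exposure_time` must be positive.")
  if (!(control_recovery > 0 && control_recovery <= 1)) {
    abort("`control_recovery` must be in (0, 1].")
  }
  structure(list(densities = as.integer(densities),
                 replicates = as.integer(replicates),
                 exposure_time = exposure_time,
                 treatments = tibble::as_tibble(treatments),
                 include_controls = include_controls,
                 control_recovery = control_recovery),
            class = "fr_design")
}

#' Default generating parameters per treatment
#'
#' Flexible-model truths matching the magnitudes reported for a mononchid
#' predator feeding on two size classes of *C. elegans* with and without
#' moss substrate: search coefficient `b` (per day), scaling exponent `q`
#' and handling time `h` (days per prey) per treatment. At a 4-hour
#' (`1/6`-day) exposure these produce the saturating consumption levels
#' typical of such trials (tens of prey eaten at the highest densities).
#'
#' @return A tibble with columns `prey_size`, `substrate`, `model`, `a`,
#'   `b`, `q`, `h` (unused parameters `NA`).
#' @export
fr_default_truth <- function() {
  tibble::tibble(
    prey_size = c("small", "large", "small", "large"),
    substrate = c("absent", "absent", "present", "present"),
    model = "flexible",
    a = NA_real_,
    b = c(0.173, 0.814, 0.781, 0.433),
    q = c(0.739, 0.362, 0.426, 0.438),
    h = c(0.003, 0.006, 0.003, 0.004))
}

#' Construct a single-treatment generating truth
#'
#' @param model `"typeII"` or `"flexible"`.
#' @param a,b,q,h Model parameters (see [fr_predict_typeII()]).
#' @param prey_size,substrate Treatment labels.
#' @return A one-row truth tibble compatible with [fr_simulate_trials()].
#' @export
fr_truth <- function(model = c("typeII", "flexible"), a = NA, b = NA, q = NA,
                     h = NA, prey_size = "small", substrate = "absent") {
  model <- match.arg(model)
  if (model == "typeII") check_positive(a, "a") else {
    check_positive(b, "b")
    if (!is.numeric(q) || q <= -1) abort("`q` must be > -1.")
  }
  check_nonneg(h, "h")
  tibble::tibble(prey_size = prey_size, substrate = substrate, model = model,
                 a = as.numeric(a), b = as.numeric(b), q = as.numeric(q),
                 h = as.numeric(h))
}

#' Simulate feeding-trial vial counts
#'
#' Generates one row per vial under the statistical structure the fitting
#' machinery assumes: in predator vials the number eaten is binomial with
#' index `N0` and success probability equal to the model-predicted
#' proportion consumed, and the final count is `N0` minus the number eaten;
#' in control vials each prey is recovered independently with probability
#' `control_recovery`. Output is deterministic given `seed` and uses the
#' same column layout [fr_read_trials()] reads.
#'
#' @param design An [fr_design()] specification.
#' @param truth A truth tibble ([fr_default_truth()] or [fr_truth()] rows)
#'   covering every treatment in the design.
#' @param seed Optional integer seed.
#' @return A tibble of simulated trials (predator and control vials).
#' @examples
#' trials <- fr_simulate_trials(seed = 1)
#' nrow(trials)   # 528 under the default design
#' @export
fr_simulate_trials <- function(design = fr_design(), truth = fr_default_truth(),
                               seed = NULL) {
  stopifnot(inherits(design, "fr_design"))
  if (!is.null(seed)) set.seed(seed)
  missing_tr <- dplyr::anti_join(design$treatments, truth,
                                 by = c("prey_size", "substrate"))
  if (nrow(missing_tr) > 0) {
    abort(sprintf("`truth` lacks treatment(s): %s",
                  paste(sprintf("%s/%s", missing_tr$prey_size,
                                missing_tr$substrate), collapse = "; ")))
  }
  grid <- tidyr::expand_grid(
    design$treatments,
    nominal_density = design$densities,
    replicate = seq_len(design$replicates))
  grid <- dplyr::left_join(grid, truth, by = c("prey_size", "substrate"))
  pred_expect <- purrr::pmap_dbl(grid, function(nominal_density, model,
                                                a, b, q, h, ...) {
    if (model == "typeII") {
      fr_predict_typeII(nominal_density, design$exposure_time, a = a, h = h)
    } else {
      fr_predict_flexible(nominal_density, design$exposure_time,
                          b = b, q = q, h = h)
    }
  })
  p_eat <- pred_expect / grid$nominal_density
  eaten <- rbinom(nrow(grid), grid$nominal_density, p_eat)
  predators <- grid |>
    dplyr::transmute(.data$prey_size, .data$substrate, .data$nominal_density,
                     .data$replicate, predator_present = TRUE,
                     final_count = as.integer(.data$nominal_density - eaten))
  if (!design$include_controls) return(predators)
  controls <- grid |>
    dplyr::transmute(.data$prey_size, .data$substrate, .data$nominal_density,
                     .data$replicate, predator_present = FALSE,
                     final_count = as.integer(
                       rbinom(dplyr::n(), .data$nominal_density,
                              design$control_recovery)))
  dplyr::bind_rows(predators, controls) |>
    dplyr::arrange(.data$prey_size, .data$substrate, .data$nominal_density,
                   dplyr::desc(.data$predator_present), .data$replicate)
}

#' Mechanistic stochastic foraging simulation
#'
#' Independent oracle for the depletion models: an alternating renewal
#' process in which the predator searches for an exponential waiting time
#' with rate `a_eff` times the prey remaining, then pauses for a fixed
#' handling time `h` after each capture, until `time` runs out. Its mean
#' number of captures approximates (but does not exactly equal) the
#' deterministic depletion solution.
#'
#' @inheritParams fr_implicit_residual
#' @param seed Optional integer seed.
#' @return Integer number of prey captured.
#' @examples
#' fr_simulate_foraging(a_eff = 1, h = 0.01, initial = 50, time = 4, seed = 1)
#' @export
fr_simulate_foraging <- function(a_eff, h, initial, time, seed = NULL) {
  check_positive(a_eff, "a_eff")
  check_nonneg(h, "h")
  check_nonneg(initial, "initial")
  check_nonneg(time, "time")
  if (!is.null(seed)) set.seed(seed)
  remaining <- initial
  t_now <- 0
  captures <- 0L
  while (remaining > 0) {
    wait <- rexp(1, rate = a_eff * remaining)
    if (t_now + wait >= time) break
    t_now <- t_now + wait
    captures <- captures + 1L
    remaining <- remaining - 1
    t_now <- t_now + h
    if (t_now >= time) break
  }
  captures
}
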