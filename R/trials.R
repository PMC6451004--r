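#' Read feeding-trial records from CSV
#'
#' One row per vial. Required columns: `prey_size` (small/large), `substrate`
#' (absent/present), `nominal_density` (positive integer), `replicate`
#' (integer), `predator_present` (logical), `final_count` (non-negative
#' integer). Labels are normalized to canonical lower-case values; common
#' synonyms (`yes`/`no`, `with`/`without`, `0`/`1`) are accepted.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble of trials with canonical column types.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' readr::write_csv(fr_simulate_trials(seed = 1), csv)
#' trials <- fr_read_trials(csv)
#' @export
fr_read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("prey_size", "substrate", "nominal_density", "replicate",
                "predator_present", "final_count")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warn("Trial file contains headers only; returning an empty table.")
    return(tibble::tibble(
      prey_size = character(), substrate = character(),
      nominal_density = integer(), replicate = integer(),
      predator_present = logical(), final_count = integer()
    ))
  }
  out <- tibble::tibble(
    prey_size = normalize_label(raw$prey_size, c(
      small = "small", large = "large"), "prey_size"),
    substrate = normalize_label(raw$substrate, c(
      absent = "absent", present = "present", without = "absent",
      with = "present", no = "absent", yes = "present",
      none = "absent", moss = "present"), "substrate"),
    nominal_density = parse_count(raw$nominal_density, "nominal_density"),
    replicate = parse_count(raw$replicate, "replicate"),
    predator_present = parse_flag(raw$predator_present, "predator_present"),
    final_count = parse_count(raw$final_count, "final_count")
  )
  bad <- which(out$final_count < 0)
  if (length(bad) > 0) {
    abort(sprintf("final_count < 0 in row(s): %s", paste(bad, collapse = ", ")))
  }
  bad <- which(out$nominal_density <= 0)
  if (length(bad) > 0) {
    abort(sprintf("nominal_density must be positive in row(s): %s",
                  paste(bad, collapse = ", ")))
  }
  out
}

normalize_label <- function(x, map, column) {
  key <- tolower(trimws(x))
  val <- unname(map[key])
  bad <- which(is.na(val) | is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("Unknown %s label %s in row(s): %s", column,
                  paste(unique(sQuote(x[bad])), collapse = ", "),
                  paste(bad, collapse = ", ")))
  }
  val
}

parse_count <- function(x, column) {
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) | num != round(num))
  if (length(bad) > 0) {
    abort(sprintf("Non-integer %s in row(s): %s", column,
                  paste(bad, collapse = ", ")))
  }
  as.integer(num)
}

parse_flag <- function(x, column) {
  key <- tolower(trimws(x))
  map <- c(`true` = TRUE, `false` = FALSE, t = TRUE, f = FALSE,
           yes = TRUE, no = FALSE, `1` = TRUE, `0` = FALSE)
  val <- unname(map[key])
  bad <- which(is.na(val))
  if (length(bad) > 0) {
    abort(sprintf("Cannot parse %s in row(s): %s", column,
                  paste(bad, collapse = ", ")))
  }
  val
}

#' Correct initial densities against predator-free controls
#'
#' For every treatment-by-density cell, the corrected initial density is the
#' mean final count over that cell's predator-free control vials, rounded
#' half-to-even to an integer so the binomial likelihood has an integer
#' index. Prey eaten in each predator vial is the corrected initial minus the
#' vial's final count, clamped into `[0, corrected_initial]`: vials that end
#' with more prey than the control mean (counting noise) score zero eaten,
#' and losses beyond the corrected initial are capped symmetrically. Control
#' vials are consumed by this step and not emitted.
#'
#' @param trials A tibble of trials, as returned by [fr_read_trials()] or
#'   [fr_simulate_trials()], containing both predator and control vials.
#' @param exposure_time Exposure duration, carried per row, in the time
#'   unit the response-model rates use — days by convention here (default
#'   `1/6`, the standard 4-hour trial).
#' @return A tibble of prepared trials: `prey_size`, `substrate`,
#'   `nominal_density`, `replicate`, `corrected_initial`, `eaten`,
#'   `exposure_time` — one row per predator vial.
#' @examples
#' trials <- fr_simulate_trials(seed = 1)
#' prepared <- fr_prepare_trials(trials)
#' @export
fr_prepare_trials <- function(trials, exposure_time = 1 / 6) {
  if (!is.numeric(exposure_time) || exposure_time <= 0) {
    abort("`exposure_time` must be positive.")
  }
  controls <- dplyr::filter(trials, !.data$predator_present)
  predators <- dplyr::filter(trials, .data$predator_present)
  if (nrow(predators) == 0) abort("No predator vials in `trials`.")
  ctrl_means <- controls |>
    dplyr::group_by(.data$prey_size, .data$substrate, .data$nominal_density) |>
    dplyr::summarise(corrected_initial = as.integer(round(mean(.data$final_count))),
                     .groups = "drop")
  out <- dplyr::left_join(
    predators, ctrl_means,
    by = c("prey_size", "substrate", "nominal_density")
  )
  if (anyNA(out$corrected_initial)) {
    miss <- dplyr::distinct(
      out[is.na(out$corrected_initial),
          c("prey_size", "substrate", "nominal_density")])
    abort(sprintf(
      "Predator vials without matching controls: %s",
      paste(sprintf("%s/%s@%d", miss$prey_size, miss$substrate,
                    miss$nominal_density), collapse = "; ")))
  }
  if (any(out$corrected_initial == 0)) {
    warn("All-zero controls for some cells; corrected initial and eaten set to 0.")
  }
  eaten_raw <- out$corrected_initial - out$final_count
  n_neg <- sum(eaten_raw < 0)
  n_over <- sum(eaten_raw > out$corrected_initial)
  if (n_neg > 0) {
    inform(sprintf("Clamped %d negative consumption value(s) to zero.", n_neg))
  }
  if (n_over > 0) {
    inform(sprintf("Capped %d consumption value(s) at the corrected initial.", n_over))
  }
  out |>
    dplyr::mutate(
      eaten = as.integer(pmin(pmax(eaten_raw, 0L), .data$corrected_initial)),
      exposure_time = exposure_time
    ) |>
    dplyr::select("prey_size", "substrate", "nominal_density", "replicate",
                  "corrected_initial", "eaten", "exposure_time")
}
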