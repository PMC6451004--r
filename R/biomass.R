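#' Nematode fresh biomass from body dimensions
#'
#' The Andrassy volumetric formula: fresh mass in micrograms from maximum
#' body width and length in micrometres,
#' \deqn{\mathrm{mass}_{\mu g} = \mathrm{width}^2 \times \mathrm{length} / 1{,}600{,}000.}
#' Dry mass is conventionally taken as 25% of fresh mass (the specific
#' gravity of 1.13 underlying the constant is metadata only; it does not
#' enter the arithmetic).
#'
#' @param length Body length(s) in micrometres (non-negative).
#' @param width Maximum body width(s) in micrometres (non-negative).
#' @return Fresh mass in micrograms (vectorized).
#' @examples
#' fr_biomass_andrassy(length = 1000, width = 40)   # 1 ug
#' @export
fr_biomass_andrassy <- function(length, width) {
  check_nonneg(length, "length")
  check_nonneg(width, "width")
  width^2 * length / 1.6e6
}

#' @rdname fr_biomass_andrassy
#' @param fresh_mass Fresh mass in micrograms.
#' @export
fr_dry_from_fresh <- function(fresh_mass) 0.25 * fresh_mass

#' @rdname fr_biomass_andrassy
#' @param dry_mass Dry mass in micrograms.
#' @export
fr_fresh_from_dry <- function(dry_mass) dry_mass / 0.25

#' Ingestion and biomass accounting for prepared trials
#'
#' Converts per-vial prey consumption into ingested biomass and extrapolates
#' to a daily per-capita rate: `ingested_dry = eaten * prey_dry_mass`,
#' `ingested_fresh = ingested_dry / 0.25`, `daily_fresh = ingested_fresh /
#' exposure_time` (exposure in days, so a 4-hour vial scales by 6), and the
#' ratio of daily fresh ingestion to the predator's own fresh mass.
#' Treatment-level summaries give the mean and maximum of each quantity.
#'
#' @param prepared A prepared-trials tibble.
#' @param prey_dry_mass Dry mass of one prey item, micrograms (positive).
#' @param predator_fresh_mass Predator fresh mass, micrograms (positive).
#' @return A list with `trials` (per-vial tibble adding `ingested_dry`,
#'   `ingested_fresh`, `daily_fresh`, `biomass_ratio`) and `treatments`
#'   (per-treatment mean and max of each).
#' @examples
#' prepared <- fr_prepare_trials(fr_simulate_trials(seed = 1))
#' fr_ingestion_summary(prepared, prey_dry_mass = 0.009,
#'                      predator_fresh_mass = 4.6)$treatments
#' @export
fr_ingestion_summary <- function(prepared, prey_dry_mass, predator_fresh_mass) {
  check_positive(prey_dry_mass, "prey_dry_mass")
  check_positive(predator_fresh_mass, "predator_fresh_mass")
  if (any(prepared$exposure_time <= 0)) abort("`exposure_time` must be positive.")
  trials <- prepared |>
    dplyr::mutate(
      ingested_dry = .data$eaten * prey_dry_mass,
      ingested_fresh = fr_fresh_from_dry(.data$ingested_dry),
      daily_fresh = .data$ingested_fresh / .data$exposure_time,
      biomass_ratio = .data$daily_fresh / predator_fresh_mass)
  treatments <- trials |>
    dplyr::group_by(.data$prey_size, .data$substrate) |>
    dplyr::summarise(
      dplyr::across(c("ingested_dry", "ingested_fresh", "daily_fresh",
                      "biomass_ratio"),
                    list(mean = mean, max = max)),
      .groups = "drop")
  list(trials = trials, treatments = treatments)
}
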