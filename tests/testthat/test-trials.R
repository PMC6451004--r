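write_trial_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(rows, path)
  path
}

trial_row <- function(prey_size = "small", substrate = "absent",
                      nominal_density = 30, replicate = 1,
                      predator_present = TRUE, final_count = 20) {
  tibble::tibble(prey_size = prey_size, substrate = substrate,
                 nominal_density = nominal_density, replicate = replicate,
                 predator_present = predator_present,
                 final_count = final_count)
}

test_that("trial CSVs round-trip with label normalization", {
  rows <- dplyr::bind_rows(
    trial_row("Small", "without", 5, 1, TRUE, 3),
    trial_row("large", "Present", 10, 2, FALSE, 10),
    trial_row("small", "yes", 30, 3, TRUE, 25))
  got <- fr_read_trials(write_trial_csv(rows))
  expect_equal(nrow(got), 3)
  expect_identical(got$prey_size, c("small", "large", "small"))
  expect_identical(got$substrate, c("absent", "present", "present"))
  expect_identical(got$final_count, c(3L, 10L, 25L))
  expect_identical(got$predator_present, c(TRUE, FALSE, TRUE))
  # full simulated table survives a write/read cycle unchanged
  sim <- fr_simulate_trials(seed = 7)
  expect_equal(fr_read_trials(write_trial_csv(sim)), sim)
})

test_that("malformed trial files fail with the offending row named", {
  bad <- dplyr::bind_rows(trial_row(), trial_row(final_count = -1))
  expect_error(fr_read_trials(write_trial_csv(bad)), "row\\(s\\): 2")
  unk <- trial_row(prey_size = "medium")
  expect_error(fr_read_trials(write_trial_csv(unk)), "Unknown prey_size")
  noint <- trial_row(final_count = "3.5")
  expect_error(fr_read_trials(write_trial_csv(noint)), "Non-integer")
  expect_error(
    fr_read_trials(write_trial_csv(dplyr::select(trial_row(), -replicate))),
    "Missing required column")
  expect_error(fr_read_trials(tempfile()), "not found")
})

test_that("headers-only files give an empty table with a warning", {
  path <- write_trial_csv(trial_row()[0, ])
  expect_warning(got <- fr_read_trials(path), "headers only")
  expect_equal(nrow(got), 0)
  expect_named(got, c("prey_size", "substrate", "nominal_density",
                      "replicate", "predator_present", "final_count"))
})

control_block <- function(finals, density = 30) {
  purrr::imap_dfr(finals, function(fc, i) {
    trial_row(nominal_density = density, replicate = i,
              predator_present = FALSE, final_count = fc)
  })
}

test_that("control means correct initial densities (round half-to-even)", {
  trials <- dplyr::bind_rows(
    control_block(c(29, 28, 30, 27, 29, 28)),     # mean 28.5 -> 28
    trial_row(final_count = 20))
  got <- fr_prepare_trials(trials)
  expect_equal(nrow(got), 1)
  expect_identical(got$corrected_initial, 28L)
  expect_identical(got$eaten, 8L)
  # mean 29.5 rounds up to the even 30
  trials2 <- dplyr::bind_rows(
    control_block(c(29, 30)), trial_row(final_count = 20))
  expect_identical(fr_prepare_trials(trials2)$corrected_initial, 30L)
})

test_that("consumption is clamped into [0, corrected_initial]", {
  # predator vial richer than the control mean scores zero eaten
  trials <- dplyr::bind_rows(control_block(rep(28, 6)),
                             trial_row(final_count = 31))
  expect_message(got <- fr_prepare_trials(trials), "Clamped 1")
  expect_identical(got$eaten, 0L)
  expect_identical(got$corrected_initial, 28L)
})

test_that("perfect controls reproduce nominal densities exactly", {
  sim <- fr_simulate_trials(seed = 11)   # control_recovery = 1
  got <- fr_prepare_trials(sim)
  expect_identical(got$corrected_initial, got$nominal_density)
  expect_equal(nrow(got), sum(sim$predator_present))
  expect_true(all(got$eaten >= 0 & got$eaten <= got$corrected_initial))
  expect_identical(got$eaten,
                   got$corrected_initial -
                     sim$final_count[sim$predator_present])
})

test_that("noisy controls still never emit out-of-range consumption", {
  design <- fr_design(replicates = 4, control_recovery = 0.9)
  sim <- fr_simulate_trials(design, seed = 5)
  got <- suppressMessages(fr_prepare_trials(sim))
  expect_true(all(got$eaten >= 0 & got$eaten <= got$corrected_initial))
  expect_equal(nrow(got), sum(sim$predator_present))
})

test_that("missing controls and all-zero controls are handled", {
  expect_error(fr_prepare_trials(trial_row()), "without matching controls")
  zero <- dplyr::bind_rows(control_block(rep(0, 3)), trial_row(final_count = 0))
  expect_warning(got <- fr_prepare_trials(zero), "All-zero controls")
  expect_identical(got$corrected_initial, 0L)
  expect_identical(got$eaten, 0L)
  expect_error(fr_prepare_trials(trial_row(), exposure_time = 0), "positive")
})
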