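#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles everything [fr_run_pipeline()] needs: either a CSV of real trials
#' (`input`) or a simulation design and generating truth, the models to fit,
#' the bootstrap size, the significance level, the seed and the output
#' directory.
#'
#' @param out_dir Output directory (created if needed).
#' @param input Optional path to a trial CSV; when `NULL`, trials are
#'   simulated from `design` and `truth`.
#' @param design An [fr_design()] specification (used when simulating).
#' @param truth A generating-truth tibble (used when simulating).
#' @param models Character vector of models to fit.
#' @param n_boot Bootstrap resamples for confidence bands (default 2000).
#' @param alpha Significance level in (0, 1).
#' @param seed Integer seed recorded in every output artifact.
#' @param band_densities Density grid for curve bands (default: 50 points
#'   spanning the design densities).
#' @return A validated list of class `fr_run_config`.
#' @export
fr_run_config <- function(out_dir, input = NULL, design = fr_design(),
                          truth = fr_default_truth(),
                          models = c("typeII", "flexible"), n_boot = 2000,
                          alpha = 0.05, seed = 1, band_densities = NULL) {
  bad <- setdiff(models, c("typeII", "flexible"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown model name(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(models) == 0) abort("`models` must name at least one model.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  if (n_boot < 0) abort("`n_boot` must be non-negative.")
  if (!is.null(input) && !file.exists(input)) {
    abort(sprintf("Input file not found: %s", input))
  }
  structure(list(out_dir = out_dir, input = input, design = design,
                 truth = truth, models = models, n_boot = as.integer(n_boot),
                 alpha = alpha, seed = as.integer(seed),
                 band_densities = band_densities),
            class = "fr_run_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Recognized keys (all optional except `out_dir`): `input`, `densities`,
#' `replicates`, `exposure_time`, `control_recovery`, `models`, `n_boot`,
#' `alpha`, `seed`, `out_dir`.
#'
#' @param path Path to a YAML file of scalar/vector keys.
#' @return An `fr_run_config`.
#' @export
fr_read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) abort("Config must set `out_dir`.")
  design <- fr_design(
    densities = y$densities %||% c(5, 10, 15, 20, 30, 50, 75, 100, 150, 200, 300),
    replicates = y$replicates %||% 6,
    exposure_time = y$exposure_time %||% 4,
    control_recovery = y$control_recovery %||% 1)
  fr_run_config(
    out_dir = y$out_dir, input = y$input, design = design,
    models = y$models %||% c("typeII", "flexible"),
    n_boot = y$n_boot %||% 2000, alpha = y$alpha %||% 0.05,
    seed = y$seed %||% 1)
}

#' Run the full functional-response analysis pipeline
#'
#' Simulate (or read) trials, correct initial densities against controls,
#' then per treatment: polynomial logistic shape diagnostics, maximum-
#' likelihood fits of the requested depletion models, AICc comparison, and
#' a bootstrap confidence band for the preferred model; finally pairwise
#' cross-treatment parameter comparisons. Writes five CSV artifacts
#' (`shape_tests.csv`, `model_selection.csv`, `parameter_estimates.csv`,
#' `treatment_comparisons.csv`, `curve_bands.csv`) and a `manifest.json`
#' recording the seed, configuration and output checksums. Any stage
#' failure aborts with the stage name; artifacts already written are kept.
#'
#' @param config An [fr_run_config()] (or path handled by
#'   [fr_read_config()]).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @examples
#' \donttest{
#' cfg <- fr_run_config(out_dir = tempfile(), n_boot = 50, seed = 1,
#'                      design = fr_design(replicates = 2))
#' res <- fr_run_pipeline(cfg)
#' }
#' @export
fr_run_pipeline <- function(config) {
  if (is.character(config)) config <- fr_read_config(config)
  stopifnot(inherits(config, "fr_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  trials <- stage("ingest", {
    if (is.null(config$input)) {
      fr_simulate_trials(config$design, config$truth, seed = config$seed)
    } else {
      fr_read_trials(config$input)
    }
  })
  prepared <- stage("preprocess",
                    fr_prepare_trials(trials, config$design$exposure_time))
  treatments <- dplyr::distinct(prepared, .data$prey_size, .data$substrate)
  shape_rows <- list(); sel_rows <- list(); est_rows <- list()
  band_rows <- list(); fits <- list()
  dens <- config$band_densities %||%
    seq(min(config$design$densities), max(config$design$densities),
        length.out = 50)
  for (i in seq_len(nrow(treatments))) {
    tr <- treatments[i, ]
    label <- sprintf("%s_%s", tr$prey_size, tr$substrate)
    sub <- dplyr::semi_join(prepared, tr, by = c("prey_size", "substrate"))
    inform(sprintf("[%s] shape diagnostics", label))
    shp <- stage("shape", {
      lin <- fr_shape_test(sub, degree = 1)
      quad <- fr_shape_test(sub, degree = 2)
      cls <- fr_classify_shape(lin, quad, alpha = config$alpha)
      dplyr::bind_rows(
        dplyr::mutate(tidy(lin), degree = 1),
        dplyr::mutate(tidy(quad), degree = 2)) |>
        dplyr::mutate(treatment = label,
                      classification = cls$classification)
    })
    shape_rows[[label]] <- shp
    inform(sprintf("[%s] maximum-likelihood fits", label))
    trt_fits <- stage("fit", {
      lapply(setNames(config$models, config$models), function(m) {
        fr_fit(sub, model = m, seed = config$seed + i)
      })
    })
    fits[[label]] <- trt_fits
    est_rows[[label]] <- purrr::imap_dfr(trt_fits, function(f, m) {
      dplyr::mutate(tidy(f), model = m, treatment = label, .before = 1)
    })
    preferred <- config$models[[1]]
    if (all(c("typeII", "flexible") %in% config$models)) {
      cmp <- stage("select",
                   fr_compare_models(trt_fits$typeII, trt_fits$flexible))
      sel_rows[[label]] <- dplyr::mutate(cmp, treatment = label, .before = 1)
      preferred <- cmp$preferred
    }
    if (config$n_boot > 0) {
      inform(sprintf("[%s] bootstrap (%d resamples) of the %s model",
                     label, config$n_boot, preferred))
      band_rows[[label]] <- stage("bootstrap", {
        boot <- fr_bootstrap(trt_fits[[preferred]], n_boot = config$n_boot,
                             seed = config$seed + 100 + i)
        dropped <- boot$n_requested - boot$n_converged
        if (dropped > 0) {
          warn(sprintf("[%s] dropped %d non-converged bootstrap replicates",
                       label, dropped))
        }
        fr_curve_band(boot, dens, time = config$design$exposure_time) |>
          dplyr::mutate(treatment = label, model = preferred, .before = 1)
      })
    }
  }
  cmp_rows <- stage("compare", {
    contrasts <- list(
      c("small_absent", "large_absent"),
      c("small_present", "large_present"),
      c("small_absent", "small_present"),
      c("large_absent", "large_present"))
    have <- sprintf("%s_%s", treatments$prey_size, treatments$substrate)
    purrr::map_dfr(contrasts, function(ct) {
      if (!all(ct %in% have)) return(NULL)
      split_lab <- strsplit(ct, "_")
      pa <- dplyr::filter(prepared, .data$prey_size == split_lab[[1]][1],
                          .data$substrate == split_lab[[1]][2])
      pb <- dplyr::filter(prepared, .data$prey_size == split_lab[[2]][1],
                          .data$substrate == split_lab[[2]][2])
      model <- if ("flexible" %in% config$models) "flexible" else "typeII"
      fr_compare_treatments(pa, pb, model = model, seed = config$seed) |>
        dplyr::mutate(contrast = paste(ct, collapse = " vs "), .before = 1)
    })
  })
  outputs <- list(
    shape_tests = dplyr::bind_rows(shape_rows),
    model_selection = dplyr::bind_rows(sel_rows),
    parameter_estimates = dplyr::bind_rows(est_rows),
    treatment_comparisons = cmp_rows,
    curve_bands = dplyr::bind_rows(band_rows))
  paths <- character(0)
  stage("report", {
    for (nm in names(outputs)) {
      if (is.null(outputs[[nm]]) || nrow(outputs[[nm]]) == 0) next
      p <- file.path(config$out_dir, paste0(nm, ".csv"))
      readr::write_csv(outputs[[nm]], p)
      paths[nm] <- p
    }
  })
  manifest <- stage("manifest", {
    cfg_plain <- list(
      input = config$input, models = config$models, n_boot = config$n_boot,
      alpha = config$alpha, seed = config$seed,
      densities = config$design$densities,
      replicates = config$design$replicates,
      exposure_time = config$design$exposure_time,
      control_recovery = config$design$control_recovery)
    m <- list(
      package = "funcresp",
      version = as.character(utils::packageVersion("funcresp")),
      seed = config$seed,
      config = cfg_plain,
      config_hash = hash_object(cfg_plain),
      output_md5 = as.list(tools::md5sum(unname(paths))) |>
        setNames(names(paths)))
    jsonlite::write_json(m, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })
  invisible(c(outputs, list(fits = fits, manifest = manifest)))
}

hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
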