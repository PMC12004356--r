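# Plain-text file formats and the end-to-end pipeline driver.
#
# Spectral matrix format: tab-delimited text; optional leading comment lines
# starting with '#'; the first data row is the strictly increasing
# wavenumber axis (cm^-1); every following row is one sample/pixel spectrum
# (intensity, a.u.). Sample metadata travels in a CSV sidecar.

#' Write a spectral matrix to delimited text
#'
#' @param data Tibble with a `spectra` matrix column (metadata columns are
#'   written to `metadata_path`), or a plain matrix with wavenumber
#'   colnames.
#' @param path Output file.
#' @param metadata_path Optional CSV sidecar for the non-spectral columns;
#'   default: `path` with a `_meta.csv` suffix when metadata exists.
#' @param comment Optional character vector written as leading `#` lines
#'   (e.g. the run seed).
#' @return `path`, invisibly.
#' @export
write_spectral_matrix <- function(data, path, metadata_path = NULL,
                                  comment = NULL) {
  X <- get_spectra_matrix(data)
  wn <- spectra_wavenumbers(data)
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  fmt <- function(v) paste(formatC(v, format = "g", digits = 15), collapse = "\t")
  lines <- c(lines, fmt(wn),
             vapply(seq_len(nrow(X)), function(i) fmt(X[i, ]), character(1)))
  writeLines(lines, path)
  if (is.data.frame(data)) {
    meta <- data[setdiff(names(data), "spectra")]
    if (ncol(meta)) {
      if (is.null(metadata_path)) {
        metadata_path <- paste0(sub("\\.[^.]*$", "", path), "_meta.csv")
      }
      if (!is.null(comment)) writeLines(paste0("# ", comment), metadata_path)
      suppressWarnings(utils::write.table(
        meta, metadata_path, sep = ",", row.names = FALSE, quote = FALSE,
        append = !is.null(comment)))
    }
  }
  invisible(path)
}

#' Read a spectral matrix written by [write_spectral_matrix()]
#'
#' Validates the format strictly: all rows must have the same field count
#' (ragged rows are reported by line number), every cell must parse as a
#' number (reported by line and column), and the axis row must be strictly
#' increasing.
#'
#' @param path Spectral matrix file.
#' @param metadata_path Optional CSV sidecar; default: the `_meta.csv`
#'   sibling if it exists.
#' @return A tibble with any metadata columns plus a `spectra` matrix
#'   column (wavenumber colnames).
#' @export
read_spectral_matrix <- function(path, metadata_path = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("file needs an axis row and >= 1 spectrum row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    abort(sprintf("ragged row %d: %d fields, expected %d", bad, nf[bad], nf[1]))
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      j <- which(is.na(vals[[i]]))[1]
      abort(sprintf("non-numeric cell at row %d, column %d: '%s'",
                    i, j, fields[[i]][j]))
    }
  }
  wn <- vals[[1]]
  if (is.unsorted(wn, strictly = TRUE)) {
    abort("axis row (row 1) must be strictly increasing")
  }
  X <- do.call(rbind, vals[-1])
  colnames(X) <- format_wn(wn)
  if (is.null(metadata_path)) {
    cand <- paste0(sub("\\.[^.]*$", "", path), "_meta.csv")
    if (file.exists(cand)) metadata_path <- cand
  }
  out <- if (!is.null(metadata_path)) {
    tibble::as_tibble(utils::read.csv(metadata_path, comment.char = "#"))
  } else {
    tibble::tibble(.rows = nrow(X))
  }
  if (nrow(out) != nrow(X)) {
    abort("metadata row count does not match the spectra matrix")
  }
  out$spectra <- X
  out
}

#' Default pipeline configuration
#'
#' Parameter blocks for every stage of [run_pipeline()]. Any block can be
#' partially overridden; unspecified entries keep their defaults.
#'
#' @param seed Global integer seed; per-stage seeds are derived from it by
#'   fixed offsets so stages are independently reproducible.
#' @param generator Arguments for [generator_config()].
#' @param reduction Arguments for [reduction_config()].
#' @param calibration `levels`, `replicates`, `test_replicates`,
#'   `n_blanks`, `n_pixels`.
#' @param model `scaling`, `max_lv`, `cv_folds`.
#' @param validation `n_folds` (leave-group-out groups over the patient
#'   cohort), `permutations` (B).
#' @param agreement `n_patients`, `reference_error_sd`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            generator = list(),
                            reduction = list(),
                            calibration = list(),
                            model = list(),
                            validation = list(),
                            agreement = list()) {
  cfg <- list(
    seed = as.integer(seed),
    generator = generator,
    reduction = reduction,
    calibration = modifyList(
      list(levels = c(25, 50, 100, 250, 500, 750), replicates = 5,
           test_replicates = 2, n_blanks = 8, n_pixels = 100),
      calibration),
    model = modifyList(list(scaling = "minmax", max_lv = 10, cv_folds = 5),
                       model),
    validation = modifyList(list(n_folds = 12, permutations = 199),
                            validation),
    agreement = modifyList(list(n_patients = 27, reference_error_sd = 5),
                           agreement)
  )
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, log_con, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain on synthetic data: simulate a calibration
#' design, an independent test set and blank replicates; fit the PLSR
#' calibration and its figures of merit; run the permutation test; simulate
#' a patient cohort, quantify each patient by leave-group-out PLSR on the
#' patient spectra (reference values as y), and compare the aggregated
#' out-of-fold predictions against the reference method with Bland-Altman
#' statistics. All artifacts are written as delimited text stamped with the
#' seed and a config hash; a rerun with the same config is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`calibration`,
#'   `model`, `fom`, `permutation`, `lgo`, `agreement`, paths).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config()")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stamp <- sprintf("seed: %d; config_hash: %s", seed, rlang::hash(config))
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  note("# %s", stamp)

  gen_cfg <- run_stage("simulate", NULL,
                       do.call(generator_config, config$generator))
  red_cfg <- do.call(reduction_config, config$reduction)
  cal_par <- config$calibration

  cal <- run_stage("simulate", NULL, generate_calibration_dataset(
    levels = cal_par$levels, replicates = cal_par$replicates,
    n_pixels = cal_par$n_pixels, config = gen_cfg, reduction = red_cfg,
    seed = seed + 1L))
  test <- run_stage("simulate", NULL, generate_calibration_dataset(
    levels = cal_par$levels, replicates = cal_par$test_replicates,
    n_pixels = cal_par$n_pixels, config = gen_cfg, reduction = red_cfg,
    seed = seed + 2L))
  blanks <- run_stage("simulate", NULL, generate_calibration_dataset(
    levels = 0, replicates = cal_par$n_blanks,
    n_pixels = cal_par$n_pixels, config = gen_cfg, reduction = red_cfg,
    seed = seed + 3L))
  note("simulate: %d calibration, %d test, %d blank spectra (%d pixels/map)",
       nrow(cal), nrow(test), nrow(blanks), cal_par$n_pixels)
  write_spectral_matrix(cal, file.path(out_dir, "calibration_spectra.txt"),
                        comment = stamp)

  mod_par <- config$model
  model <- run_stage("calibrate", NULL, plsr_fit(
    cal, scaling = mod_par$scaling, max_lv = mod_par$max_lv,
    cv_folds = mod_par$cv_folds))
  fom <- run_stage("calibrate", NULL,
                   figures_of_merit(model, test, blank_data = blanks))
  note("calibrate: selected %d LV, RMSEC %.4g uM", model$lv,
       model$rmsec[model$lv])
  fom_tbl <- tidy(fom)
  fom_out <- data.frame(
    parameter = c("RMSEP", "BIAS", "SEP", "SEN", "gamma", "gamma_inverse",
                  "LoD", "LoQ", "R2_calibration", "R2_cross_validation",
                  "R2_prediction"),
    unit = c("uM", "uM", "uM", "scaled_intensity_per_uM", "1_per_uM", "uM",
             "uM", "uM", "unitless", "unitless", "unitless"),
    value = unlist(fom_tbl[c("rmsep", "bias", "sep", "sen", "gamma",
                             "gamma_inverse", "lod", "loq", "r2_cal",
                             "r2_cv", "r2_pred")])
  )
  write_delim_stamped(fom_out, file.path(out_dir, "figures_of_merit.tsv"),
                      stamp)
  coef_tbl <- tidy(model)
  names(coef_tbl) <- c("wavenumber_cm1", "coefficient_uM_per_scaled_intensity")
  write_delim_stamped(as.data.frame(coef_tbl),
                      file.path(out_dir, "model_coefficients.tsv"), stamp)
  write_delim_stamped(as.data.frame(glance(model)),
                      file.path(out_dir, "model_summary.tsv"), stamp)

  val_par <- config$validation
  perm <- run_stage("validate", NULL, permutation_test(
    cal, B = val_par$permutations, seed = seed + 4L,
    scaling = mod_par$scaling, max_lv = mod_par$max_lv,
    cv_folds = mod_par$cv_folds))
  note("validate: permutation p = %.4g (B = %d)", perm$p_value, perm$B)
  write_delim_stamped(
    data.frame(statistic_unit = "unitless", null_value = perm$null),
    file.path(out_dir, "permutation_null.tsv"), stamp)

  agr_par <- config$agreement
  cohort <- run_stage("agree", NULL, generate_paired_cohort(
    n_patients = agr_par$n_patients,
    reference_error_sd = agr_par$reference_error_sd,
    test_error_sd = 0, test_bias = 0, seed = seed + 5L))
  patient_maps <- run_stage("agree", NULL, with_seed(seed + 6L, {
    red <- purrr::map(cohort$truth, function(cc) {
      gm <- generate_map_matrix(cc, cal_par$n_pixels, gen_cfg)
      reduce_matrix_top_fraction(gm$X, gm$wavenumbers, red_cfg)
    })
    sp <- do.call(rbind, purrr::map(red, "spectrum"))
    colnames(sp) <- format_wn(red[[1]]$wavenumbers)
    out <- cohort["patient"]
    out$concentration <- cohort$reference  # y for LGO is the reference method
    out$spectra <- sp
    out
  }))
  plan <- run_stage("validate", NULL, make_fold_plan(
    agr_par$n_patients, val_par$n_folds, seed = seed + 7L))
  lgo <- run_stage("validate", NULL, leave_group_out_plsr(
    patient_maps, plan, scaling = mod_par$scaling,
    max_lv = mod_par$max_lv, cv_folds = mod_par$cv_folds))
  note("validate: leave-group-out over %d folds, pooled RMSEP %.4g uM",
       lgo$n_folds, lgo$rmsep)

  paired <- tibble::tibble(patient = cohort$patient,
                           reference = cohort$reference,
                           test = lgo$predictions$predicted)
  agreement <- run_stage("agree", NULL,
                         bland_altman(paired, reference, test))
  note("agree: bias %.3g uM, LoA [%.3g, %.3g] uM, MDC %.3g uM",
       agreement$bias, agreement$lla, agreement$ula, agreement$mdc)
  agr_out <- glance(agreement)
  write_delim_stamped(
    data.frame(parameter = names(agr_out),
               unit = c("pairs", "uM", "uM", "uM", "uM", "uM", "mg_per_L",
                        "pairs", "unitless", "unitless"),
               value = unlist(agr_out)),
    file.path(out_dir, "agreement.tsv"), stamp)
  write_delim_stamped(as.data.frame(paired),
                      file.path(out_dir, "paired_concentrations_uM.tsv"),
                      stamp)

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(calibration = cal, test = test, blanks = blanks,
                 model = model, fom = fom, permutation = perm,
                 cohort = cohort, fold_plan = plan, lgo = lgo,
                 agreement = agreement, out_dir = out_dir))
}

write_delim_stamped <- function(df, path, stamp) {
  writeLines(paste0("# ", stamp), path)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 15))
  suppressWarnings(utils::write.table(df, path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(path)
}
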