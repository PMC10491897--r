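# File formats and the end-to-end pipeline: plain delimited-text spectra
# tables with JSON-lines metadata sidecars, a validated YAML run
# configuration, and the simulate -> preprocess -> QF filter -> grid search ->
# evaluate workflow.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

# Derive a named substream seed from the master seed (kept below 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream * 7919) %% 2147483647)
}

#' Write a synthetic cohort as delimited text plus JSON-lines metadata
#'
#' One tab-separated table per measurement (pixel index, one column per
#' repeat frame, the dark frame, and the ground-truth pure Raman, background
#' and response columns), a `metadata.jsonl` sidecar with one JSON object per
#' measurement, a `reference.tsv` with the calibration and broadband frames,
#' and a `cohort.json` with the generating configuration. Numbers are written
#' with 17 significant digits so the round trip is exact.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.jsonl")
  meta_con <- file(meta_path, "w")
  on.exit(close(meta_con))
  for (i in seq_along(cohort$measurements)) {
    m <- cohort$measurements[[i]]
    fname <- sprintf("meas_%04d.tsv", i)
    nr <- ncol(m$repeat_frames)
    header <- c("pixel", sprintf("rep_%d", seq_len(nr)), "dark",
                "pure_raman", "background", "response")
    tab <- cbind(seq_len(nrow(m$repeat_frames)), m$repeat_frames,
                 m$dark_frame, m$truth$pure_raman, m$truth$background,
                 m$truth$applied_response)
    lines <- c(paste(header, collapse = "\t"),
               apply(tab, 1, function(r) paste(fmt_num(r), collapse = "\t")))
    writeLines(lines, file.path(dir, fname))
    writeLines(jsonlite::toJSON(list(
      id = i, file = fname, patient_id = m$patient_id, label = m$label,
      category = m$category, quality = m$quality,
      noise_level = m$truth$noise_level, gain = m$truth$gain
    ), auto_unbox = TRUE, digits = NA), meta_con)
  }
  ref <- cohort$reference
  ref_tab <- cbind(seq_along(ref$calibration_frame), ref$calibration_frame,
                   ref$broadband_frame, ref$certified_shape, ref$wavenumbers)
  writeLines(c(paste(c("pixel", "calibration_frame", "broadband_frame",
                       "certified_shape", "wavenumber_truth"),
                     collapse = "\t"),
               apply(ref_tab, 1, function(r) paste(fmt_num(r), collapse = "\t"))),
             file.path(dir, "reference.tsv"))
  jsonlite::write_json(
    list(config = unclass(cohort$config),
         reference_wavenumbers = ref$reference_wavenumbers),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Parse one delimited spectra table; errors name the offending row.
parse_spectra_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop(sprintf("no measurements in '%s'", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncols <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncols) {
      stop(sprintf("ragged row %d in '%s': %d fields, expected %d",
                   i, path, length(rows[[i]]), ncols))
    }
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncols)))
  bad <- which(apply(is.na(vals), 2, any))
  if (length(bad)) {
    stop(sprintf("non-numeric cell in row %d of '%s'", bad[1], path))
  }
  tab <- t(vals)
  colnames(tab) <- header
  tab
}

#' Read one spectra table and its metadata sidecar
#'
#' @param path path to a per-measurement `.tsv` written by [write_cohort()].
#' @param metadata optional pre-parsed metadata record (list); otherwise the
#'   `metadata.jsonl` sidecar in the same directory is consulted.
#' @return a `simulated_measurement`-shaped record.
#' @export
read_spectra_table <- function(path, metadata = NULL) {
  tab <- parse_spectra_table(path)
  if (is.null(metadata)) {
    side <- file.path(dirname(path), "metadata.jsonl")
    if (!file.exists(side)) stop(sprintf("missing metadata sidecar '%s'", side))
    recs <- lapply(readLines(side), jsonlite::fromJSON)
    hit <- which(vapply(recs, `[[`, character(1), "file") == basename(path))
    if (!length(hit)) stop(sprintf("no metadata record for '%s'", basename(path)))
    metadata <- recs[[hit[1]]]
  }
  rep_cols <- grep("^rep_", colnames(tab))
  structure(list(
    repeat_frames = tab[, rep_cols, drop = FALSE],
    dark_frame = tab[, "dark"],
    patient_id = metadata$patient_id, label = metadata$label,
    category = metadata$category, quality = metadata$quality,
    truth = list(pure_raman = tab[, "pure_raman"],
                 background = tab[, "background"],
                 applied_response = tab[, "response"],
                 noise_level = metadata$noise_level, gain = metadata$gain)
  ), class = "simulated_measurement")
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `raman_cohort`-shaped list (measurements, reference, config).
#' @export
read_cohort <- function(dir) {
  side <- file.path(dir, "metadata.jsonl")
  if (!file.exists(side)) stop(sprintf("missing metadata sidecar '%s'", side))
  recs <- lapply(readLines(side), jsonlite::fromJSON)
  if (!length(recs)) stop("no measurements")
  measurements <- lapply(recs, function(md) {
    read_spectra_table(file.path(dir, md$file), metadata = md)
  })
  ref_tab <- parse_spectra_table(file.path(dir, "reference.tsv"))
  meta <- jsonlite::fromJSON(file.path(dir, "cohort.json"))
  reference <- list(calibration_frame = ref_tab[, "calibration_frame"],
                    broadband_frame = ref_tab[, "broadband_frame"],
                    certified_shape = ref_tab[, "certified_shape"],
                    wavenumbers = ref_tab[, "wavenumber_truth"],
                    reference_wavenumbers = meta$reference_wavenumbers)
  config <- do.call(cohort_config, meta$config)
  structure(list(measurements = measurements, reference = reference,
                 config = config),
            class = "raman_cohort")
}

#' Run configuration with validation
#'
#' Nested configuration for [run_pipeline()]. Unknown keys are rejected with
#' a message naming them.
#'
#' @param config named list of overrides (possibly nested), e.g. parsed from
#'   a YAML file by [read_run_config()].
#' @return validated configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  cohort_defaults <- unclass(cohort_config())
  cohort_defaults$seed <- NULL  # the run seed drives the cohort substream
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    cohort = cohort_defaults,
    preprocess = preprocess_params(),
    quality = list(qf_threshold = 0.4, smooth_window = 9, poly_order = 1),
    model = list(C_grid = c(0.01, 0.05, 0.1, 0.5, 1, 2, 5),
                 k_min = 5, k_max = 20, exclude = c(1060, 1100)),
    evaluate = list(n_permutations = 100, permutation_patient_level = FALSE)
  )
  merged <- defaults
  for (key in names(config)) {
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown configuration key '%s'", key))
    }
    if (is.list(defaults[[key]])) {
      for (sub in names(config[[key]])) {
        if (!sub %in% names(defaults[[key]])) {
          stop(sprintf("unknown configuration key '%s.%s'", key, sub))
        }
        v <- config[[key]][[sub]]
        if (is.list(v)) v <- unlist(v)  # YAML sequences arrive as lists
        merged[[key]][[sub]] <- v
      }
    } else {
      merged[[key]] <- config[[key]]
    }
  }
  q <- merged$quality$qf_threshold
  if (!is.null(q) && (q < 0 || q > 1)) stop("qf_threshold must be in [0, 1]")
  if (merged$model$k_min < 1 || merged$model$k_max < merged$model$k_min) {
    stop("invalid feature-count grid")
  }
  if (any(merged$model$C_grid <= 0)) stop("C_grid values must be > 0")
  structure(merged, class = "run_config")
}

#' Read and validate a YAML run configuration
#' @param path YAML file.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Simulate a cohort, preprocess every measurement, filter by quality factor,
#' fit the LOPO-validated cancer-detection model with its hyperparameter grid
#' search, and evaluate (ROC, permutation null, univariate band statistics,
#' cohort tallies). All randomness flows from `config$seed` through named
#' substreams (cohort, permutations). If `config$out_dir` is set, every
#' artifact (cohort tables, processed spectra, QC report, model, evaluation
#' report, run log) is written there; rerunning with an identical
#' configuration reproduces identical artifacts.
#'
#' @param config a [run_config()] (a plain list is validated first).
#' @return object of class `raman_report`: `qc`, `model`, `roc`,
#'   `permutation`, `band_stats`, `tally`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out_dir <- config$out_dir
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("qf_threshold: %s", config$quality$qf_threshold),
                 sprintf("exclude_interval: %s",
                         paste(config$model$exclude, collapse = "-")),
                 sprintf("C_grid: %s",
                         paste(config$model$C_grid, collapse = ", ")),
                 sprintf("k_grid: %d-%d", config$model$k_min,
                         config$model$k_max),
                 sprintf("n_permutations: %d",
                         config$evaluate$n_permutations))

  cc <- do.call(cohort_config,
                c(config$cohort, list(seed = derive_seed(config$seed, 1))))
  cohort <- with_stage("simulate", generate_cohort(cc))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
  }

  params <- do.call(preprocess_params,
                    config$preprocess[c("min_bubble_width", "axis_step",
                                        "response_smooth_window",
                                        "snv_before_baseline")])
  ds <- with_stage("preprocess",
                   preprocess_cohort(cohort, params,
                                     qf_window = config$quality$smooth_window,
                                     qf_order = config$quality$poly_order))
  if (!is.null(out_dir)) write_processed(ds, file.path(out_dir, "processed"))

  qc <- with_stage("qc", split_by_qf(ds, config$quality$qf_threshold))$summary
  model <- with_stage("train",
                      raman_cancer_model(ds,
                                         qf_threshold = config$quality$qf_threshold,
                                         exclude_interval = config$model$exclude,
                                         C_grid = config$model$C_grid,
                                         k_grid = config$model$k_min:config$model$k_max))
  perm <- NULL
  if (config$evaluate$n_permutations >= 2) {
    retained <- split_by_qf(ds, config$quality$qf_threshold)$retained
    fm <- build_feature_matrix(retained, config$model$exclude)
    perm <- with_stage("evaluate",
                       permutation_null(fm, C = model$best$C, k = model$best$k,
                                        n_repeats = config$evaluate$n_permutations,
                                        seed = derive_seed(config$seed, 2),
                                        patient_level = config$evaluate$permutation_patient_level))
  }
  retained <- split_by_qf(ds, config$quality$qf_threshold)$retained
  bands <- with_stage("evaluate", band_statistics(retained))
  tally <- with_stage("evaluate",
                      tally_cohort(as_count_vector(qc$acquired_by_category),
                                   as_count_vector(qc$retained_by_category)))

  report <- structure(list(qc = qc, model = model, roc = model$roc,
                           permutation = perm, band_stats = bands,
                           tally = tally, config = unclass(config)),
                      class = "raman_report")
  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run.log"))
    write_report_json(report, out_dir)
  }
  report
}

as_count_vector <- function(tab) {
  stats::setNames(as.integer(tab), names(tab))
}

write_processed <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_con <- file(file.path(dir, "metadata.jsonl"), "w")
  on.exit(close(meta_con))
  for (i in seq_len(n_spectra(ds))) {
    fname <- sprintf("spec_%04d.tsv", i)
    tab <- cbind(ds$axis, ds$snv[i, ], ds$raman[i, ])
    writeLines(c("wavenumber\tsnv_intensity\traman_before_snv",
                 apply(tab, 1, function(r) paste(fmt_num(r), collapse = "\t"))),
               file.path(dir, fname))
    writeLines(jsonlite::toJSON(list(
      id = i, file = fname, patient_id = ds$patient_id[i],
      label = as.character(ds$label[i]), category = ds$category[i],
      quality = ds$quality[i], qf = ds$qf[i]
    ), auto_unbox = TRUE, digits = NA), meta_con)
  }
  invisible(dir)
}

write_report_json <- function(report, out_dir) {
  qc <- report$qc
  jsonlite::write_json(list(
    n_total = qc$n_total, n_retained = qc$n_retained,
    n_rejected = qc$n_rejected, rejected_fraction = qc$rejected_fraction,
    threshold = qc$threshold,
    acquired_by_category = as.list(as_count_vector(qc$acquired_by_category)),
    retained_by_category = as.list(as_count_vector(qc$retained_by_category)),
    class_ratio_before = qc$class_ratio_before,
    class_ratio_after = qc$class_ratio_after
  ), file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)

  m <- report$model
  jsonlite::write_json(list(
    hyperparameters = m$best[c("C", "k")],
    selected_wavenumbers = m$selected_wavenumbers,
    weights = unname(m$final$weights), intercept = m$final$intercept,
    per_fold_selected = m$cv$selected, flagged_folds = m$cv$flagged,
    seed = report$config$seed
  ), file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)

  op <- report$roc$operating_point
  cfg <- report$config
  cfg$out_dir <- NULL  # path-independent artifacts stay byte-comparable
  ev <- list(
    auc = report$roc$auc,
    operating_point = op,
    band_stats = report$band_stats,
    tally = unclass(report$tally),
    config = cfg
  )
  if (!is.null(report$permutation)) {
    ev$permutation <- list(n_repeats = report$permutation$n_repeats,
                           mean_auc = report$permutation$mean_auc,
                           sd_auc = report$permutation$sd_auc)
  }
  jsonlite::write_json(ev, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' @export
print.raman_report <- function(x, ...) {
  print(x$qc)
  print(x$model)
  if (!is.null(x$permutation)) print(x$permutation)
  invisible(x)
}
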