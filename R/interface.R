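# File I/O (vessel-tree JSON, cohort CSV, frozen-parameter JSON, YAML run
# configuration) and end-to-end virtual-trial orchestration:
# simulate -> calibrate -> freeze & apply -> evaluate.

#' Write a vessel tree to JSON
#'
#' Schema: `vessel_label`, `segments` (each with `id`, `parent_id`,
#' `samples` as `[arc_mm, r_lumen_mm, r_ref_mm]` triples, `is_outlet`), and
#' `lesions`.  Numbers are written at full precision so a round trip
#' reproduces the tree exactly.
#'
#' @param tree A `coro_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  tree <- validate_tree(tree)
  obj <- list(
    vessel_label = tree$vessel_label,
    segments = lapply(unname(tree$segments), function(s) list(
      id = s$id, parent_id = s$parent_id,
      samples = cbind(s$arc, s$r_lumen, s$r_ref),
      is_outlet = s$is_outlet)),
    lesions = lapply(tree$lesions, unclass))
  # 17 significant digits: exact binary64 round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @keywords internal
schema_fail <- function(pointer, what) {
  stop(sprintf("vessel-tree JSON schema violation at %s: %s", pointer, what),
       call. = FALSE)
}

#' Read a vessel tree from JSON
#'
#' Validates the schema on load; violations raise an error carrying a
#' JSON-pointer-style path to the offending field.
#'
#' @param path File written by [write_tree_json()].
#' @return A `coro_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (is.null(obj$vessel_label)) schema_fail("/vessel_label", "missing")
  if (is.null(obj$segments) || !length(obj$segments))
    schema_fail("/segments", "missing or empty")
  segs <- lapply(seq_along(obj$segments), function(i) {
    s <- obj$segments[[i]]
    ptr <- sprintf("/segments/%d", i - 1L)
    for (f in c("id", "samples", "is_outlet"))
      if (is.null(s[[f]])) schema_fail(paste0(ptr, "/", f), "missing")
    samples <- s$samples
    if (is.list(samples)) samples <- do.call(rbind, samples)
    if (!is.matrix(samples) || ncol(samples) != 3)
      schema_fail(paste0(ptr, "/samples"),
                  "must be an array of [arc_mm, r_lumen_mm, r_ref_mm] triples")
    structure(list(id = as.character(s$id),
                   parent_id = if (is.null(s$parent_id) || is.na(s$parent_id))
                     NA_character_ else as.character(s$parent_id),
                   arc = as.numeric(samples[, 1]),
                   r_lumen = as.numeric(samples[, 2]),
                   r_ref = as.numeric(samples[, 3]),
                   is_outlet = isTRUE(as.logical(s$is_outlet))),
              class = "coro_segment")
  })
  lesions <- lapply(seq_along(obj$lesions %||% list()), function(i) {
    l <- obj$lesions[[i]]
    ptr <- sprintf("/lesions/%d", i - 1L)
    for (f in c("segment_id", "start", "length", "degree"))
      if (is.null(l[[f]])) schema_fail(paste0(ptr, "/", f), "missing")
    lesion(l$segment_id, l$start, l$length, l$degree,
           l$calcified_volume %||% 0, l$noncalcified_volume %||% 0,
           l$calcium_score %||% 0)
  })
  vessel_tree(segs, obj$vessel_label, lesions)
}

#' Write frozen boundary parameters to JSON
#'
#' @param x A [boundary_params()] or a fitted `ffr_cal` (whose fitted
#'   parameters, free set, training MSE and seed are recorded).
#' @param path Output file path.
#' @param seed Optional run seed recorded in the artifact.
#' @return `path`, invisibly.
#' @export
write_theta_json <- function(x, path, seed = NULL) {
  obj <- if (inherits(x, "ffr_cal")) {
    list(theta = unclass(x$theta), free = x$free, mse = x$mse,
         n_cases = x$n_cases, seed = x$seed, converged = x$converged)
  } else {
    stopifnot(inherits(x, "boundary_params"))
    list(theta = unclass(x))
  }
  if (!is.null(seed)) obj$run_seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read frozen boundary parameters from JSON
#'
#' @param path File written by [write_theta_json()].
#' @return A [boundary_params()]; calibration metadata, when present, is
#'   attached as attribute `"calibration"`.
#' @export
read_theta_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- obj$theta
  if (is.null(th)) stop("theta JSON missing /theta", call. = FALSE)
  params <- boundary_params(P_a = th$P_a, R_ref = th$R_ref, d_ref = th$d_ref,
                            k = th$k, K_t = th$K_t, h = th$h)
  meta <- obj[setdiff(names(obj), "theta")]
  if (length(meta)) attr(params, "calibration") <- meta
  params
}

#' @keywords internal
COHORT_REQUIRED_COLUMNS <- c("vessel_id", "vessel_label", "measured_ffr",
                             "cta_percent_stenosis")

#' Write a cohort table to CSV
#'
#' UTF-8, comma-separated, '.' decimal, mandatory header row; the run seed
#' and configuration hash are carried in '#' comment lines above the header.
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @param seed Run seed recorded in the header.
#' @param config_hash Configuration hash recorded in the header.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, seed = NA, config_hash = NA) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", seed), con)
  writeLines(sprintf("# config_hash: %s", config_hash), con)
  utils::write.table(cohort, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path File written by [write_cohort_csv()] (comment lines allowed).
#' @param required Columns that must be present; a missing one raises an
#'   error naming it.
#' @return The cohort data.frame; header `seed` is attached as an attribute
#'   when present.
#' @export
read_cohort_csv <- function(path, required = COHORT_REQUIRED_COLUMNS) {
  first <- readLines(path, n = 10)
  seed <- sub("^# seed: ", "", grep("^# seed: ", first, value = TRUE)[1])
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("cohort CSV missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!is.na(seed)) attr(df, "seed") <- seed
  df
}

#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  # hash the scientific configuration only; output location is irrelevant
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  jsonlite::write_json(rapply(cfg, unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * stage) %% 2147483647)
}

#' Virtual-trial run configuration
#'
#' @param seed Master run seed; per-stage substreams are derived from it so
#'   toggling one stage does not shift the others.
#' @param n_train Retrospective training vessels for calibration.
#' @param n_vessels Prospective cohort size.
#' @param cohort A [cohort_config()] template (its `n_vessels`/`seed` are
#'   overridden per stage).
#' @param policy A [threshold_policy()].
#' @param free,n_starts,maxit Calibration settings passed to
#'   [calibrate_ffr()].
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
trial_config <- function(seed = 1L, n_train = 80L, n_vessels = 400L,
                         cohort = cohort_config(), policy = threshold_policy(),
                         free = c("R_ref", "k", "K_t"), n_starts = 8L,
                         maxit = 600L, out_dir = "trial_report") {
  if (n_vessels <= 0)
    stop("n_vessels must be positive", call. = FALSE)
  if (n_train < 5)
    stop("n_train below 5 cannot support calibration", call. = FALSE)
  structure(list(seed = as.integer(seed), n_train = as.integer(n_train),
                 n_vessels = as.integer(n_vessels), cohort = cohort,
                 policy = policy, free = free, n_starts = as.integer(n_starts),
                 maxit = as.integer(maxit), out_dir = out_dir),
            class = "run_config")
}

#' Load a virtual-trial configuration from YAML
#'
#' Recognized top-level keys: `seed`, `n_train`, `n_vessels`, `out_dir`,
#' `n_starts`, `maxit`, `free`, plus nested `cohort:` and `policy:` blocks
#' whose keys mirror [cohort_config()] and [threshold_policy()] arguments.
#'
#' @param path YAML file path.
#' @return A [trial_config()].
#' @export
read_trial_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  policy <- do.call(threshold_policy, y$policy %||% list())
  args <- y[intersect(names(y), c("seed", "n_train", "n_vessels", "free",
                                  "n_starts", "maxit", "out_dir"))]
  do.call(trial_config, c(args, list(cohort = cohort, policy = policy)))
}

#' Run a complete virtual trial
#'
#' End-to-end orchestration at synthetic scale: (1) generate a retrospective
#' training cohort and calibrate the boundary parameters on it, (2) freeze
#' the fit, (3) generate the prospective cohort and compute CT-FFR for every
#' vessel with the frozen parameters, (4) evaluate the full
#' diagnostic-performance analysis, and (5) write the report bundle (cohort
#' CSV, frozen-theta JSON, metric/bin/stratum/OR CSVs, JSON summary, and a
#' provenance manifest with seed and config hash).  Stage failures raise an
#' error naming the stage.
#'
#' @param config A [trial_config()].
#' @param write Write the report bundle to `config$out_dir`?
#' @return Invisibly, a list with `cohort`, `fit`, `evaluation`, `manifest`
#'   and (when written) `paths`.
#' @export
run_virtual_trial <- function(config = trial_config(), write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("virtual-trial stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  hash <- config_hash(config)

  train_cfg <- config$cohort
  train_cfg$n_vessels <- config$n_train
  train_cfg$seed <- stage_seed(config$seed, 1L)
  train <- stage("simulate-train", generate_cohort(train_cfg))

  fit <- stage("calibrate",
    calibrate_ffr(cohort_training_cases(train), free = config$free,
                  n_starts = config$n_starts, maxit = config$maxit,
                  seed = stage_seed(config$seed, 2L)))

  prosp_cfg <- config$cohort
  prosp_cfg$n_vessels <- config$n_vessels
  prosp_cfg$seed <- stage_seed(config$seed, 3L)
  prospective <- stage("simulate-cohort", generate_cohort(prosp_cfg))

  applied <- stage("apply", freeze_and_apply(fit, prospective$vessels))
  cohort <- prospective$cohort
  cohort$ct_ffr <- applied$ct_ffr[match(cohort$vessel_id, applied$vessel_id)]
  cohort$ct_ffr_note <- applied$note[match(cohort$vessel_id, applied$vessel_id)]

  evaluation <- stage("evaluate", evaluate_cohort(cohort, config$policy))

  manifest <- list(seed = config$seed, config_hash = hash,
                   package_version = as.character(utils::packageVersion("ctffr")),
                   n_train = config$n_train, n_vessels = config$n_vessels,
                   stage_seeds = list(train = train_cfg$seed,
                                      calibrate = stage_seed(config$seed, 2L),
                                      cohort = prosp_cfg$seed))
  paths <- NULL
  if (write) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      cohort = file.path(out, "cohort.csv"),
      theta = file.path(out, "theta.json"),
      metrics_ctffr = file.path(out, "metrics_ctffr.csv"),
      metrics_cta = file.path(out, "metrics_cta.csv"),
      bin_accuracy = file.path(out, "bin_accuracy.csv"),
      misdiagnosis = file.path(out, "misdiagnosis.csv"),
      or_screen = file.path(out, "or_screen.csv"),
      summary = file.path(out, "summary.json"),
      manifest = file.path(out, "manifest.json"))
    write_cohort_csv(cohort, paths$cohort, config$seed, hash)
    write_theta_json(fit, paths$theta, seed = config$seed)
    hdr <- function(df, path) {
      con <- file(path, "wt", encoding = "UTF-8")
      on.exit(close(con))
      writeLines(sprintf("# seed: %s", config$seed), con)
      writeLines(sprintf("# config_hash: %s", hash), con)
      utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
    }
    hdr(evaluation$metrics$ct_ffr, paths$metrics_ctffr)
    hdr(evaluation$metrics$cta, paths$metrics_cta)
    hdr(evaluation$bin_accuracy, paths$bin_accuracy)
    hdr(evaluation$misdiagnosis, paths$misdiagnosis)
    if (!is.null(evaluation$or_screen)) hdr(evaluation$or_screen, paths$or_screen)
    jsonlite::write_json(list(
      manifest = manifest,
      auc = list(ct_ffr = evaluation$auc$ct_ffr$auc, cta = evaluation$auc$cta$auc),
      pearson_r = evaluation$pearson$r,
      bland_altman_mean = evaluation$bland_altman$all$mean_difference,
      theta_hat = unclass(fit$theta), training_mse = fit$mse),
      paths$summary, auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(cohort = cohort, fit = fit, evaluation = evaluation,
                 manifest = manifest, paths = paths))
}
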