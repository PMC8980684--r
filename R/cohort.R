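# Seeded virtual-trial cohort generator.
#
# Each vessel is a small branching tree (proximal trunk, main continuation,
# side branch) carrying one target lesion.  The "invasive" FFR comes from
# the reference reduced-order model with a per-vessel log-normal
# microvascular perturbation plus additive measurement noise; the stenosis
# degree is solved by root-finding so the measured FFR hits a target drawn
# from a stratified marginal (ischemic / gray-zone / non-ischemic), which
# makes the configured stratum fractions structural rather than tuned.

#' Virtual-cohort configuration
#'
#' Defaults emulate the per-vessel composition of a multicenter CT-FFR
#' validation cohort: about 46.2% of vessels ischemic (FFR < 0.80) of which
#' 13.7% of all vessels fall in the 0.76-0.80 gray zone, lesions of 30-90%
#' diameter stenosis on vessels of at least 2.0 mm.
#'
#' @param n_vessels Number of vessels to generate.
#' @param vessel_label_mix Named proportions over LAD/LCX/RCA (sum to 1).
#' @param target_ischemic_fraction Fraction of vessels with FFR < 0.80.
#' @param gray_zone_fraction Fraction of all vessels with FFR in the gray
#'   zone (a subset of the ischemic fraction).
#' @param gray_zone Gray-zone FFR interval, default `c(0.76, 0.80)`.
#' @param ischemic_ffr_min Lower support of the ischemic FFR marginal.
#' @param ffr_noise_sd Additive measurement noise SD on invasive FFR.
#' @param vessel_effect_sd Log-normal SD of the per-vessel microvascular
#'   resistance perturbation.
#' @param cta_reader_sd CTA stenosis-reading noise SD, percentage points.
#' @param diameter_range Range of proximal trunk reference diameters (mm);
#'   the lower bound keeps every lesion-bearing vessel at >= 2.0 mm.
#' @param reference_theta [boundary_params()] of the reference model that
#'   generates the invasive measurements.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_vessels = 366,
                          vessel_label_mix = c(LAD = 0.6, LCX = 0.2, RCA = 0.2),
                          target_ischemic_fraction = 0.462,
                          gray_zone_fraction = 0.137,
                          gray_zone = c(0.76, 0.80),
                          ischemic_ffr_min = 0.40,
                          ffr_noise_sd = 0.02,
                          vessel_effect_sd = 0.15,
                          cta_reader_sd = 8,
                          diameter_range = c(2.4, 4.4),
                          reference_theta = boundary_params(),
                          seed = 1L) {
  if (n_vessels < 0 || n_vessels != round(n_vessels))
    stop("n_vessels must be a non-negative integer", call. = FALSE)
  if (abs(sum(vessel_label_mix) - 1) > 1e-8)
    stop("vessel_label_mix proportions must sum to 1", call. = FALSE)
  if (!setequal(names(vessel_label_mix), c("LAD", "LCX", "RCA")))
    stop("vessel_label_mix must name LAD, LCX and RCA", call. = FALSE)
  if (ffr_noise_sd < 0 || vessel_effect_sd < 0 || cta_reader_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (gray_zone_fraction > target_ischemic_fraction)
    stop("infeasible config: the gray zone is a subset of the ischemic ",
         "stratum, so gray_zone_fraction cannot exceed target_ischemic_fraction",
         call. = FALSE)
  if (target_ischemic_fraction < 0 || target_ischemic_fraction > 1)
    stop("target_ischemic_fraction must lie in [0, 1]", call. = FALSE)
  if (gray_zone[1] >= gray_zone[2] || gray_zone[2] > 1)
    stop("gray_zone must be an increasing interval within (0, 1]", call. = FALSE)
  if (ischemic_ffr_min >= gray_zone[1])
    stop("ischemic_ffr_min must lie below the gray zone", call. = FALSE)
  structure(list(n_vessels = as.integer(n_vessels),
                 vessel_label_mix = vessel_label_mix,
                 target_ischemic_fraction = target_ischemic_fraction,
                 gray_zone_fraction = gray_zone_fraction,
                 gray_zone = gray_zone, ischemic_ffr_min = ischemic_ffr_min,
                 ffr_noise_sd = ffr_noise_sd,
                 vessel_effect_sd = vessel_effect_sd,
                 cta_reader_sd = cta_reader_sd,
                 diameter_range = diameter_range,
                 reference_theta = reference_theta, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @keywords internal
perturbed_params <- function(theta, vessel_effect) {
  theta$R_ref <- theta$R_ref * vessel_effect
  theta
}

#' @keywords internal
model_ffr_at_degree <- function(tree, les0, degree, theta, offset = 25) {
  les <- les0
  les$degree <- degree
  tree$lesions <- list(les)
  sol <- solve_steady_flow(tree, theta)
  measure_ffr(sol, les, offset)$value
}

#' Simulated invasive FFR measurement
#'
#' Emulates a pressure-wire measurement: the reference reduced-order model is
#' solved with the vessel's microvascular resistance perturbed by a
#' log-normal factor (between-vessel physiology), and additive Gaussian
#' measurement noise is applied; the result is truncated to (0, 1].  Draws
#' from the current RNG stream.
#'
#' @param tree A `coro_tree` carrying the lesion.
#' @param les The target [lesion()].
#' @param reference_theta [boundary_params()] of the reference model.
#' @param vessel_effect_sd Log-normal SD of the microvascular perturbation.
#' @param noise_sd Additive measurement noise SD.
#' @param offset Probe offset distal to the lesion, mm.
#' @return Measured FFR in (0, 1].
#' @export
invasive_ffr_oracle <- function(tree, les, reference_theta = boundary_params(),
                                vessel_effect_sd = 0.15, noise_sd = 0.02,
                                offset = 25) {
  g <- exp(stats::rnorm(1, 0, vessel_effect_sd))
  e <- stats::rnorm(1, 0, noise_sd)
  m <- model_ffr_at_degree(tree, les, les$degree,
                           perturbed_params(reference_theta, g), offset)
  min(max(m + e, 1e-6), 1)
}

#' Simulated CTA stenosis reading
#'
#' Adds reader noise to the true percent diameter stenosis and truncates to
#' [0, 100); also returns the >= 50% and >= 70% category flags.  Draws from
#' the current RNG stream.
#'
#' @param true_degree True percent diameter stenosis in [0, 100).
#' @param reader_sd Reader noise SD in percentage points.
#' @return List with `percent_stenosis`, `ge50`, `ge70`.
#' @export
cta_reading <- function(true_degree, reader_sd = 8) {
  if (any(true_degree < 0 | true_degree >= 100))
    stop("true_degree must lie in [0, 100)", call. = FALSE)
  reading <- true_degree + stats::rnorm(length(true_degree), 0, reader_sd)
  reading <- pmin(pmax(reading, 0), 100 - 1e-9)
  list(percent_stenosis = reading, ge50 = reading >= 50, ge70 = reading >= 70)
}

# Stratum-conditional plaque covariates; median targets follow the rank
# pattern of published gray-zone burden tables (gray-zone plaque load above
# non-ischemic, calcified volume highest in the gray zone).
#' @keywords internal
COVARIATE_MEDIANS <- list(
  low  = c(lesion_length = 22.3, plaque_volume = 153.0,
           noncalcified_volume = 20.9, calcified_volume = 11.7),
  gray = c(lesion_length = 21.3, plaque_volume = 159.5,
           noncalcified_volume = 18.2, calcified_volume = 21.6),
  high = c(lesion_length = 17.6, plaque_volume = 87.0,
           noncalcified_volume = 12.5, calcified_volume = 7.6))

#' @keywords internal
COVARIATE_SDLOG <- c(lesion_length = 0.55, plaque_volume = 0.9,
                     noncalcified_volume = 1.0, calcified_volume = 1.8)

#' @keywords internal
draw_covariates <- function(stratum) {
  med <- COVARIATE_MEDIANS[[stratum]]
  vals <- stats::rlnorm(length(med), meanlog = log(med), sdlog = COVARIATE_SDLOG)
  names(vals) <- names(med)
  vals["calcium_score"] <- vals["calcified_volume"] *
    stats::rlnorm(1, meanlog = log(4.5), sdlog = 0.6)
  vals
}

#' @keywords internal
build_cohort_vessel <- function(label, prox_d, lesion_len) {
  # proximal trunk hosting the target lesion (it carries the full vessel
  # flow), then a main continuation and a side branch
  trunk_len <- stats::runif(1, 30, 45)
  main_len <- stats::runif(1, 40, 62)
  side_len <- stats::runif(1, 22, 32)
  d_trunk_dist <- 0.93 * prox_d
  d_main_prox <- 0.97 * d_trunk_dist
  d_main_dist <- 0.72 * d_main_prox
  d_side_prox <- 0.68 * d_trunk_dist
  tree <- build_tree(data.frame(
    id = c("prox", "main", "side"),
    parent = c(NA, "prox", "prox"),
    length = c(trunk_len, main_len, side_len),
    prox_diameter = c(prox_d, d_main_prox, d_side_prox),
    dist_diameter = c(d_trunk_dist, d_main_dist, 0.85 * d_side_prox),
    stringsAsFactors = FALSE), vessel_label = label)
  start <- stats::runif(1, 3, 6)
  len <- min(max(lesion_len, 6), trunk_len - start - 2)
  list(tree = tree, les0 = lesion("prox", start, len, degree = 50))
}

#' Generate a synthetic virtual-trial cohort
#'
#' Builds `n_vessels` diseased vessel trees, simulates the invasive FFR
#' measurement and the CTA stenosis reading for each, and draws plaque
#' covariates conditional on the FFR stratum so the stratum medians follow
#' the published rank pattern.  For each vessel a target FFR is drawn from
#' the stratified marginal (ischemic below the gray zone / gray zone /
#' non-ischemic) and the stenosis degree in [30, 90] is solved so the
#' noisy measurement equals the target; degrees clamp at the bounds.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param offset FFR probe offset distal to the lesion, mm.
#' @return A list of class `trial_cohort`: `cohort` (one row per vessel),
#'   `vessels` (list of `list(tree, les, vessel_id)`), `config`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_vessels = 10, seed = 42))
#' head(coh$cohort)
#' }
#' @export
generate_cohort <- function(config = cohort_config(), offset = 25) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_vessels
  vessels <- vector("list", n)
  rows <- vector("list", n)
  gz <- config$gray_zone
  p_low <- config$target_ischemic_fraction - config$gray_zone_fraction
  p_gray <- config$gray_zone_fraction
  with_local_seed(config$seed, {
    labels <- sample(names(config$vessel_label_mix), n, replace = TRUE,
                     prob = config$vessel_label_mix)
    for (i in seq_len(n)) {
      stratum <- {
        u <- stats::runif(1)
        if (u < p_low) "low" else if (u < p_low + p_gray) "gray" else "high"
      }
      target <- switch(stratum,
        low  = config$ischemic_ffr_min +
               (gz[1] - 1e-4 - config$ischemic_ffr_min) * stats::rbeta(1, 1.4, 1.8),
        gray = stats::runif(1, gz[1], gz[2] - 1e-4),
        high = gz[2] + 1e-4 + (0.995 - gz[2] - 1e-4) * stats::rbeta(1, 1.6, 1.1))
      cov <- draw_covariates(stratum)
      prox_d <- stats::runif(1, config$diameter_range[1], config$diameter_range[2])
      ves <- build_cohort_vessel(labels[i], prox_d, cov[["lesion_length"]])
      g <- exp(stats::rnorm(1, 0, config$vessel_effect_sd))
      e <- stats::rnorm(1, 0, config$ffr_noise_sd)
      theta_i <- perturbed_params(config$reference_theta, g)
      f <- function(deg) model_ffr_at_degree(ves$tree, ves$les0, deg,
                                             theta_i, offset) - (target - e)
      f30 <- f(30); f90 <- f(90)
      degree <- if (f30 <= 0) 30
                else if (f90 >= 0) 90
                else stats::uniroot(f, c(30, 90), f.lower = f30, f.upper = f90,
                                    tol = 5e-4)$root
      les <- ves$les0
      les$degree <- degree
      les$calcified_volume <- cov[["calcified_volume"]]
      les$noncalcified_volume <- cov[["noncalcified_volume"]]
      les$calcium_score <- cov[["calcium_score"]]
      tree <- ves$tree
      tree$lesions <- list(les)
      measured <- min(max(model_ffr_at_degree(tree, les, degree, theta_i,
                                              offset) + e, 1e-6), 1)
      cta <- cta_reading(degree, config$cta_reader_sd)
      narrowed <- apply_stenosis(tree$segments[[les$segment_id]], les)
      geom <- plaque_burden(narrowed, les)
      vid <- sprintf("v%04d", i)
      vessels[[i]] <- list(tree = tree, les = les, vessel_id = vid)
      rows[[i]] <- data.frame(
        vessel_id = vid, vessel_label = labels[i],
        measured_ffr = measured,
        degree_true = degree,
        cta_percent_stenosis = cta$percent_stenosis,
        cta_ge50 = cta$ge50, cta_ge70 = cta$ge70,
        lesion_length = les$length,
        plaque_volume = cov[["plaque_volume"]],
        calcified_volume = cov[["calcified_volume"]],
        noncalcified_volume = cov[["noncalcified_volume"]],
        plaque_burden = geom$plaque_burden_pct,
        lumen_area = geom$min_lumen_area_mm2,
        lumen_diameter = geom$min_lumen_diameter_mm,
        calcium_score = cov[["calcium_score"]],
        stringsAsFactors = FALSE)
    }
  })
  cohort <- if (n) do.call(rbind, rows)
            else data.frame(vessel_id = character(0))
  structure(list(cohort = cohort, vessels = vessels, config = config),
            class = "trial_cohort")
}

#' Designed retrospective training set for boundary-parameter calibration
#'
#' Builds a factorial calibration design: stenosis degrees spanning 30-90%
#' (weighted toward the severe range where the expansion loss carries
#' information), crossed with short and long lesions (separating the
#' flow-squared expansion loss from the integrated viscous loss) and a
#' spread of vessel calibers (separating the outlet power law from the flow
#' scale).  Measurements are the reference model's FFR plus optional
#' Gaussian noise.  An information (Jacobian) analysis of this design gives
#' markedly smaller estimator variance than a trial-mix cohort of equal
#' size, which motivates its use for parameter-recovery experiments.
#'
#' @param n Number of training vessels (the 80-point factorial grid is
#'   recycled or truncated to `n`).
#' @param theta Reference [boundary_params()] generating the measurements.
#' @param noise_sd Additive measurement noise SD on the measured FFR.
#' @param seed Integer seed (vessel geometry jitter and noise draws).
#' @param offset FFR probe offset distal to the lesion, mm.
#' @return List of [training_case()]s.
#' @export
calibration_design <- function(n = 80, theta = boundary_params(),
                               noise_sd = 0, seed = 1, offset = 25) {
  grid <- expand.grid(degree = c(30, 45, 60, 70, 78, 84, 88, 90),
                      len = c(6, 30),
                      diam = c(2.6, 3.0, 3.4, 3.8, 4.2))
  idx <- rep_len(seq_len(nrow(grid)), n)
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      g <- grid[idx[i], ]
      v <- build_cohort_vessel("LAD", g$diam, lesion_len = g$len)
      les <- v$les0
      les$degree <- g$degree
      tree <- v$tree
      tree$lesions <- list(les)
      m <- measure_ffr(solve_steady_flow(tree, theta), les, offset)$value
      measured <- min(1, max(1e-6, m + stats::rnorm(1, 0, noise_sd)))
      training_case(tree, measured, les, sprintf("cal%03d", i))
    })
  })
}

#' Convert a generated cohort into calibration training cases
#'
#' @param cohort A [generate_cohort()] result.
#' @return List of [training_case()]s pairing each vessel tree with its
#'   simulated invasive FFR.
#' @export
cohort_training_cases <- function(cohort) {
  stopifnot(inherits(cohort, "trial_cohort"))
  lapply(seq_along(cohort$vessels), function(i) {
    v <- cohort$vessels[[i]]
    training_case(v$tree, cohort$cohort$measured_ffr[i], v$les, v$vessel_id)
  })
}

#' @export
print.trial_cohort <- function(x, ...) {
  n <- nrow(x$cohort)
  isch <- mean(x$cohort$measured_ffr < 0.8)
  gz <- x$config$gray_zone
  gray <- mean(x$cohort$measured_ffr >= gz[1] & x$cohort$measured_ffr <= gz[2])
  cat(sprintf("<trial_cohort> %d vessels (seed %d): %.1f%% ischemic, %.1f%% gray zone\n",
              n, x$config$seed, 100 * isch, 100 * gray))
  invisible(x)
}

#' Generate a random vessel tree
#'
#' Random branching topology for solver stress tests: grows from a root by
#' repeatedly splitting leaves with diameter-shrinking children until the
#' requested size is reached.  Draws from the current RNG stream.
#'
#' @param n_segments Number of segments (>= 1).
#' @param prox_diameter Root proximal diameter (mm).
#' @return A `coro_tree` whose leaves are all outlets.
#' @export
random_tree <- function(n_segments, prox_diameter = 3.5) {
  stopifnot(n_segments >= 1)
  rows <- data.frame(id = "s1", parent = NA_character_,
                     length = stats::runif(1, 10, 30),
                     prox_diameter = prox_diameter,
                     dist_diameter = prox_diameter * stats::runif(1, 0.85, 0.98),
                     stringsAsFactors = FALSE)
  while (nrow(rows) < n_segments) {
    leaves <- setdiff(rows$id, rows$parent)
    pid <- sample(leaves, 1)
    d_par <- rows$dist_diameter[rows$id == pid]
    n_kids <- min(if (stats::runif(1) < 0.6) 2L else 1L, n_segments - nrow(rows))
    for (j in seq_len(n_kids)) {
      d0 <- d_par * stats::runif(1, 0.6, 0.95)
      rows <- rbind(rows, data.frame(
        id = sprintf("s%d", nrow(rows) + 1L), parent = pid,
        length = stats::runif(1, 8, 25),
        prox_diameter = d0, dist_diameter = d0 * stats::runif(1, 0.75, 0.95),
        stringsAsFactors = FALSE))
    }
  }
  build_tree(rows)
}
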