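# Boundary-parameter calibration: fit the reduced-order model's boundary
# conditions to invasively measured FFR by minimizing the mean squared error
# over a retrospective training set, then freeze the fit for prospective use.

#' Bundle one retrospective training case
#'
#' @param tree A `coro_tree` carrying the target lesion in `tree$lesions`
#'   (or pass it via `les`).
#' @param les The target [lesion()]; defaults to the tree's first lesion.
#' @param measured_ffr Invasively measured FFR in (0, 1].
#' @param vessel_id Optional identifier.
#' @return A list of class `training_case`.
#' @export
training_case <- function(tree, measured_ffr, les = NULL, vessel_id = NA_character_) {
  if (is.null(les)) {
    if (!length(tree$lesions))
      stop("tree carries no lesion and `les` not given", call. = FALSE)
    les <- tree$lesions[[1]]
  }
  if (!is.finite(measured_ffr) || measured_ffr <= 0 || measured_ffr > 1)
    stop("measured_ffr must lie in (0, 1]", call. = FALSE)
  structure(list(tree = tree, les = les, measured_ffr = measured_ffr,
                 vessel_id = vessel_id),
            class = "training_case")
}

# Precompile a case: network plus the measurement stencil (host segment of
# the probe after the downstream path walk, interpolated cumulative viscous
# coefficient, and which expansion losses act proximal to the probe).  This
# makes each objective evaluation a single network solve plus O(1) algebra.
#' @keywords internal
compile_case <- function(case, blood = blood_model(), offset = 25,
                         profile = "cosine") {
  net <- compile_network(case$tree, blood, profile)
  les <- case$les
  i <- match(les$segment_id, net$ids)
  target <- les$start + les$length + offset
  repeat {
    L <- segment_length(net$tree$segments[[i]])
    if (target <= L + 1e-9) break
    kids <- net$children[[i]]
    if (!length(kids)) { target <- L; break }
    d_dist <- vapply(kids, function(j) {
      s <- net$tree$segments[[j]]
      s$r_ref[length(s$r_ref)]
    }, numeric(1))
    target <- target - L
    i <- kids[which.max(d_dist)]
  }
  seg <- net$tree$segments[[i]]
  target <- min(target, segment_length(seg))
  a_cum_s <- stats::approx(seg$arc, net$a_cum[[i]], xout = target)$y
  b_active <- if (length(net$throats[[i]]))
    sum(net$b_parts[[i]][net$throats[[i]] <= target + 1e-12]) else 0
  list(net = net, meas_idx = i, a_cum_s = a_cum_s, b_unit_active = b_active,
       measured_ffr = case$measured_ffr, les = les,
       vessel_id = case$vessel_id)
}

#' @keywords internal
compiled_case_ffr <- function(ccase, params, tol = 1e-8, max_iter = 200) {
  sol <- solve_network(ccase$net, params, tol, max_iter)
  i <- ccase$meas_idx
  q <- sol$Q[i]
  p <- sol$P_prox[i] - q * ccase$a_cum_s -
    params$K_t * ccase$b_unit_active * q * abs(q)
  p / params$P_a
}

#' Mean squared error between computed and measured FFR
#'
#' @param theta A [boundary_params()].
#' @param cases List of [training_case()]s (or precompiled cases).
#' @param blood A [blood_model()].
#' @param offset Probe offset distal to the lesion, mm.
#' @return Mean over cases of (computed - measured)^2.
#' @export
ffr_mse <- function(theta, cases, blood = blood_model(), offset = 25) {
  if (!length(cases)) stop("need at least one training case", call. = FALSE)
  compiled <- lapply(cases, function(cs)
    if (inherits(cs, "training_case")) compile_case(cs, blood, offset) else cs)
  computed <- vapply(compiled, compiled_case_ffr, numeric(1), params = theta)
  measured <- vapply(compiled, `[[`, numeric(1), "measured_ffr")
  mean((computed - measured)^2)
}

#' @keywords internal
default_calibration_bounds <- function() {
  list(R_ref = c(50, 1000), k = c(0, 6), K_t = c(0, 8), h = c(1, 10))
}

#' Calibrate boundary-condition parameters against measured FFR
#'
#' Fits the free boundary parameters by bounded multi-start derivative-free
#' minimization of [ffr_mse()]: `n_starts` Latin-hypercube initial points in
#' the box bounds, Nelder-Mead on a logistic transform of the box, and a
#' polishing restart from the best start.  Deterministic for a fixed `seed`.
#'
#' `h` is excluded from the default free set because only `R_ref / h` enters
#' the model, so `h` and `R_ref` are not jointly identifiable.
#'
#' @param cases List of [training_case()]s (>= 5 recommended).
#' @param free Character vector naming the free parameters, a subset of
#'   `c("R_ref", "k", "K_t", "h")`.
#' @param bounds Named list of `c(lower, upper)` per free parameter; defaults
#'   span the physiologically plausible box.
#' @param n_starts Number of Latin-hypercube starts.
#' @param seed Integer seed for start placement.
#' @param base_params [boundary_params()] supplying the fixed parameters.
#' @param blood A [blood_model()].
#' @param offset Probe offset distal to the lesion, mm.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `ffr_cal` with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `simulate` and `plot`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_vessels = 20, seed = 7))
#' cases <- cohort_training_cases(coh)
#' fit <- calibrate_ffr(cases, n_starts = 2, seed = 1, maxit = 200)
#' coef(fit)
#' }
#' @export
calibrate_ffr <- function(cases, free = c("R_ref", "k", "K_t"),
                          bounds = NULL, n_starts = 8, seed = 1,
                          base_params = boundary_params(),
                          blood = blood_model(), offset = 25, maxit = 600) {
  if (!length(cases)) stop("need at least one training case", call. = FALSE)
  free <- match.arg(free, c("R_ref", "k", "K_t", "h"), several.ok = TRUE)
  all_bounds <- default_calibration_bounds()
  if (!is.null(bounds)) all_bounds[names(bounds)] <- bounds
  lower <- vapply(all_bounds[free], `[`, numeric(1), 1)
  upper <- vapply(all_bounds[free], `[`, numeric(1), 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)

  degrees <- vapply(cases, function(cs) {
    les <- if (inherits(cs, "training_case")) cs$les else cs$les
    les$degree
  }, numeric(1))
  if (diff(range(degrees)) < 20)
    warning("training set spans < 20 percentage points of stenosis degree; ",
            "free parameters may be weakly identified", call. = FALSE)

  compiled <- lapply(cases, function(cs)
    if (inherits(cs, "training_case")) compile_case(cs, blood, offset) else cs)
  measured <- vapply(compiled, `[[`, numeric(1), "measured_ffr")

  theta_from_z <- function(z) {
    th <- base_params
    th[free] <- as.list(lower + (upper - lower) * stats::plogis(z))
    th
  }
  objective <- function(z) {
    th <- theta_from_z(z)
    computed <- vapply(compiled, compiled_case_ffr, numeric(1), params = th)
    mean((computed - measured)^2)
  }

  d <- length(free)
  starts <- with_local_seed(seed, lhs::randomLHS(n_starts, d))
  z_starts <- stats::qlogis(0.02 + 0.96 * starts)   # keep starts off the box edges

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    runs[[s]] <- tryCatch(
      stats::optim(z_starts[s, ], objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) list(value = Inf, par = z_starts[s, ],
                               convergence = 1L, error = conditionMessage(e)))
  }
  values <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(values))) {
    diag <- vapply(runs, function(r) r$error %||% "non-finite objective",
                   character(1))
    stop("calibration failed on every start:\n", paste(diag, collapse = "\n"),
         call. = FALSE)
  }
  best <- which.min(values)
  polish <- stats::optim(runs[[best]]$par, objective, method = "Nelder-Mead",
                         control = list(maxit = 2L * maxit, reltol = 1e-13))
  theta_hat <- theta_from_z(polish$par)
  fitted_ffr <- vapply(compiled, compiled_case_ffr, numeric(1), params = theta_hat)

  structure(
    list(theta = theta_hat, free = free,
         bounds = all_bounds[free], mse = polish$value,
         n_cases = length(cases), converged = polish$convergence == 0L,
         starts = data.frame(start = seq_len(n_starts), mse = values),
         seed = seed, offset = offset, blood = blood,
         fitted_values = fitted_ffr, measured = measured,
         compiled = compiled, call = match.call()),
    class = "ffr_cal")
}

#' @export
coef.ffr_cal <- function(object, all = FALSE, ...) {
  th <- unlist(object$theta)
  if (all) th else th[object$free]
}

#' @export
fitted.ffr_cal <- function(object, ...) object$fitted_values

#' @export
residuals.ffr_cal <- function(object, ...) object$measured - object$fitted_values

#' Apply a frozen calibration to new vessels
#'
#' Runs the flow solve and FFR measurement with the fitted parameters,
#' unchanged, for every new vessel.  A per-vessel solver failure is recorded
#' as `NA` with its reason, not raised.
#'
#' @param object An `ffr_cal` fit.
#' @param newdata List of vessels: each a `coro_tree` carrying its lesion, a
#'   [training_case()], or a `list(tree =, les =)`.  Omitted: the training
#'   cases are re-evaluated.
#' @param ... Unused.
#' @return A data.frame with `vessel_id`, `ct_ffr`, and `note` (failure
#'   reason or `""`).
#' @export
predict.ffr_cal <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(data.frame(vessel_id = vapply(object$compiled, function(cc)
      cc$vessel_id %||% NA_character_, character(1)),
      ct_ffr = object$fitted_values, note = "", stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(newdata), function(i) {
    v <- newdata[[i]]
    id <- if (!is.null(v$vessel_id) && !is.na(v$vessel_id)) v$vessel_id
          else sprintf("v%03d", i)
    tryCatch({
      cc <- if (!is.null(v$net)) v
            else {
              cs <- if (inherits(v, "training_case")) v
                    else training_case(v$tree %||% v, measured_ffr = 1,
                                       les = v$les, vessel_id = id)
              compile_case(cs, object$blood, object$offset)
            }
      data.frame(vessel_id = id,
                 ct_ffr = compiled_case_ffr(cc, object$theta), note = "",
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(vessel_id = id, ct_ffr = NA_real_,
                 note = conditionMessage(e), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Freeze a calibration and compute CT-FFR over a cohort
#'
#' Thin named wrapper over [predict.ffr_cal()] matching the trial workflow:
#' parameters fitted retrospectively are applied, fixed, to every
#' prospective vessel.
#'
#' @param fit An `ffr_cal`.
#' @param cohort_vessels List of vessels as in [predict.ffr_cal()].
#' @return Per-vessel CT-FFR data.frame.
#' @export
freeze_and_apply <- function(fit, cohort_vessels) {
  stopifnot(inherits(fit, "ffr_cal"))
  if (!length(cohort_vessels))
    return(data.frame(vessel_id = character(0), ct_ffr = numeric(0),
                      note = character(0), stringsAsFactors = FALSE))
  predict(fit, newdata = cohort_vessels)
}

#' @export
print.ffr_cal <- function(x, ...) {
  cat("Boundary-condition calibration (reduced-order CT-FFR model)\n")
  cat(sprintf("  %d training vessels, %d starts, seed %d\n",
              x$n_cases, nrow(x$starts), x$seed))
  cat(sprintf("  training MSE: %.3e  (RMSE %.4f FFR units)\n", x$mse, sqrt(x$mse)))
  cat("  fitted parameters:\n")
  cf <- coef(x)
  for (nm in names(cf)) cat(sprintf("    %-6s %.4g\n", nm, cf[nm]))
  invisible(x)
}

#' @export
summary.ffr_cal <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object, residual_summary = summary(res),
              rmse = sqrt(object$mse),
              pearson_r = if (length(res) >= 3 && stats::sd(object$fitted_values) > 0)
                stats::cor(object$fitted_values, object$measured) else NA_real_)
  class(out) <- "summary.ffr_cal"
  out
}

#' @export
print.summary.ffr_cal <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Pearson r (computed vs measured): %.3f\n", x$pearson_r))
  cat("  residuals (measured - computed):\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
plot.ffr_cal <- function(x, ...) {
  graphics::plot(x$fitted_values, x$measured, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "computed CT-FFR", ylab = "measured FFR",
                 main = "Calibration fit", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(h = 0.8, v = 0.8, col = "grey70", lty = 3)
  invisible(x)
}

#' @export
simulate.ffr_cal <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd_hat <- stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, {
    y <- object$fitted_values + stats::rnorm(object$n_cases, 0, sd_hat)
    pmin(pmax(y, 1e-6), 1)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a temporary RNG seed, restoring the caller's state.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
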