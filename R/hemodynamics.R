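# Reduced-order steady-state coronary hemodynamics on a vessel tree.
#
# Each segment obeys the lumped loss law  dP = a*Q + b*Q*|Q|  with `a` the
# integrated Poiseuille coefficient of the (possibly narrowed) lumen and `b`
# a post-stenotic expansion loss concentrated at the lesion throat.  Outlets
# see a single microvascular resistance to zero venous pressure, allocated
# across outlets by a diameter power law and reduced by the hyperemia factor.
# Interfaces use mmHg / (mL/s) / mm; conversions go through 1 mmHg = 133.322 Pa.

PA_PER_MMHG <- 133.322
# Pa.s/m^3 -> mmHg.s/mL ; Pa/(m^3/s)^2 -> mmHg/(mL/s)^2
A_SI_TO_CLINICAL <- 1e-6 / PA_PER_MMHG
B_SI_TO_CLINICAL <- 1e-12 / PA_PER_MMHG

#' Blood rheology model
#'
#' Incompressible Newtonian blood.  Defaults: density 1060 kg/m^3
#' (1.06 g/cm^3), dynamic viscosity 0.004 Pa.s (0.04 g/cm.s).
#'
#' @param density Blood density (kg/m^3), > 0.
#' @param viscosity Dynamic viscosity (Pa.s), > 0.
#' @return An object of class `blood_model`.
#' @export
blood_model <- function(density = 1060, viscosity = 0.004) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity),
            class = "blood_model")
}

#' Boundary-condition parameter vector
#'
#' The calibratable parameters that close the reduced-order model.  None of
#' them is measurable from CTA; `R_ref`, `k` and `K_t` are the default free
#' set of [calibrate_ffr()].
#'
#' @param P_a Mean aortic (ostium) pressure, mmHg.  Held fixed per run; FFR
#'   normalizes by it.
#' @param R_ref Resting microvascular outlet resistance at the reference
#'   diameter, mmHg.s/mL.  The default gives a healthy 3.0 mm outlet about
#'   1.5 mL/s of hyperemic flow at 93 mmHg.
#' @param d_ref Reference outlet diameter for the power law, mm.
#' @param k Diameter exponent of the outlet-resistance power law
#'   (dimensionless, >= 0); 2.7 sits between area scaling and Murray's law.
#' @param K_t Turbulent (post-stenotic expansion) loss coefficient,
#'   dimensionless, >= 0.
#' @param h Hyperemia factor (>= 1): resting microvascular resistance is
#'   divided by `h`.  `h` enters only through `R_ref / h` and is therefore
#'   confounded with `R_ref`; it is excluded from calibration by default.
#' @return An object of class `boundary_params`.
#' @export
boundary_params <- function(P_a = 93, R_ref = 248, d_ref = 3.0, k = 2.7,
                            K_t = 1.0, h = 4) {
  if (P_a <= 0 || R_ref <= 0 || d_ref <= 0)
    stop("P_a, R_ref and d_ref must be positive", call. = FALSE)
  if (k < 0 || K_t < 0) stop("k and K_t must be >= 0", call. = FALSE)
  if (h < 1) stop("hyperemia factor h must be >= 1", call. = FALSE)
  structure(list(P_a = P_a, R_ref = R_ref, d_ref = d_ref, k = k,
                 K_t = K_t, h = h),
            class = "boundary_params")
}

#' Integrated Poiseuille coefficient of a segment
#'
#' Linear pressure-loss coefficient `a = integral 8 mu / (pi r(s)^4) ds`
#' over the lumen radius profile (trapezoidal over the samples), returned in
#' mmHg per mL/s.  For a uniform tube this is the closed form
#' `128 mu L / (pi d^4)`.
#'
#' @param segment A `coro_segment`.
#' @param blood A [blood_model()].
#' @return Coefficient in mmHg.s/mL.
#' @export
poiseuille_coefficient <- function(segment, blood = blood_model()) {
  validate_segment(segment)
  r_m <- segment$r_lumen * 1e-3
  s_m <- segment$arc * 1e-3
  f <- 8 * blood$viscosity / (pi * r_m^4)
  a_si <- sum(diff(s_m) * (f[-1] + f[-length(f)]) / 2)
  a_si * A_SI_TO_CLINICAL
}

#' @keywords internal
cumulative_poiseuille <- function(segment, blood) {
  r_m <- segment$r_lumen * 1e-3
  s_m <- segment$arc * 1e-3
  f <- 8 * blood$viscosity / (pi * r_m^4)
  c(0, cumsum(diff(s_m) * (f[-1] + f[-length(f)]) / 2)) * A_SI_TO_CLINICAL
}

#' Expansion-loss coefficient of a stenosis
#'
#' Quadratic loss coefficient of the post-stenotic jet expansion,
#' `b = K_t * rho/2 * (1/A_throat - 1/A_ref)^2`, with `A_throat` the minimal
#' lumen area inside the lesion and `A_ref` the local reference area,
#' returned in mmHg per (mL/s)^2.
#'
#' @param segment The narrowed `coro_segment` hosting the lesion.
#' @param les The [lesion()].
#' @param blood A [blood_model()].
#' @param K_t Turbulent loss coefficient (dimensionless).
#' @return Coefficient in mmHg/(mL/s)^2 (0 when the lumen is unnarrowed).
#' @export
turbulent_coefficient <- function(segment, les, blood = blood_model(), K_t = 1) {
  check_lesion_on_segment(segment, les)
  inside <- segment$arc >= les$start - 1e-12 &
            segment$arc <= les$start + les$length + 1e-12
  i_min <- which(inside)[which.min(segment$r_lumen[inside])]
  a_throat <- pi * (segment$r_lumen[i_min] * 1e-3)^2
  a_ref <- pi * (segment$r_ref[i_min] * 1e-3)^2
  K_t * (blood$density / 2) * (1 / a_throat - 1 / a_ref)^2 * B_SI_TO_CLINICAL
}

#' Allocate outlet resistances over a tree
#'
#' Hyperemic outlet resistance `R_i = (R_ref / h) * (d_i / d_ref)^(-k)` where
#' `d_i` is the distal reference diameter of outlet `i`.
#'
#' @param tree A `coro_tree` with at least one outlet segment.
#' @param params A [boundary_params()].
#' @return Named numeric vector of resistances (mmHg.s/mL) per outlet segment.
#' @export
assign_outlet_resistances <- function(tree, params = boundary_params()) {
  tree <- validate_tree(tree)
  outlets <- names(tree$segments)[vapply(tree$segments, `[[`, logical(1), "is_outlet")]
  if (!length(outlets))
    stop("tree has no outlet segments", call. = FALSE)
  d <- vapply(tree$segments[outlets],
              function(s) 2 * s$r_ref[length(s$r_ref)], numeric(1))
  r <- (params$R_ref / params$h) * (d / params$d_ref)^(-params$k)
  names(r) <- outlets
  r
}

# ---- network compilation -------------------------------------------------

#' Compile a vessel tree into solver form
#'
#' Precomputes everything that does not depend on the boundary parameters:
#' topology in topological order, per-segment Poiseuille coefficients and
#' cumulative profiles, per-lesion unit expansion coefficients (to be scaled
#' by `K_t`), and outlet diameters.  Lesions annotated on the tree are
#' applied to the lumen first (idempotent).
#'
#' @param tree A `coro_tree`.
#' @param blood A [blood_model()].
#' @param profile Narrowing profile for [apply_lesions()].
#' @return An object of class `coro_network`.
#' @export
compile_network <- function(tree, blood = blood_model(), profile = "cosine") {
  tree <- validate_tree(tree)
  tree <- apply_lesions(tree, profile)
  ids <- names(tree$segments)
  n <- length(ids)
  parents <- vapply(tree$segments, `[[`, character(1), "parent_id")
  parent_idx <- match(parents, ids)            # NA for root
  children <- lapply(ids, function(id) which(!is.na(parent_idx) & parents == id))
  is_leaf <- lengths(children) == 0L
  is_outlet <- vapply(tree$segments, `[[`, logical(1), "is_outlet")
  if (any(is_leaf & !is_outlet))
    stop("every terminal segment must be an outlet (dead-end branch found)",
         call. = FALSE)
  if (!any(is_outlet))
    stop("tree has no outlet segments", call. = FALSE)
  if (any(is_outlet & !is_leaf))
    stop("outlet segments must be terminal", call. = FALSE)
  # topological (root-first) order by BFS
  order <- integer(0)
  frontier <- which(is.na(parent_idx))
  while (length(frontier)) {
    order <- c(order, frontier)
    frontier <- unlist(children[frontier], use.names = FALSE)
  }
  a <- vapply(tree$segments, poiseuille_coefficient, numeric(1), blood = blood)
  a_cum <- lapply(tree$segments, cumulative_poiseuille, blood = blood)
  b_unit <- numeric(n)
  throats <- vector("list", n)
  b_parts <- vector("list", n)
  for (les in tree$lesions) {
    i <- match(les$segment_id, ids)
    bu <- turbulent_coefficient(tree$segments[[i]], les, blood, K_t = 1)
    b_unit[i] <- b_unit[i] + bu
    throats[[i]] <- c(throats[[i]], les$start + les$length / 2)
    b_parts[[i]] <- c(b_parts[[i]], bu)
  }
  d_out <- ifelse(is_outlet,
                  vapply(tree$segments, function(s) 2 * s$r_ref[length(s$r_ref)],
                         numeric(1)),
                  NA_real_)
  structure(
    list(tree = tree, ids = ids, n = n, parent_idx = parent_idx,
         children = children, order = order, is_outlet = is_outlet,
         a = unname(a), a_cum = a_cum, b_unit = b_unit,
         throats = throats, b_parts = b_parts, d_out = unname(d_out)),
    class = "coro_network")
}

#' @keywords internal
solve_network <- function(net, params, tol = 1e-8, max_iter = 200,
                          damping = 0.5) {
  n <- net$n
  order <- net$order
  rev_order <- rev(order)
  b <- params$K_t * net$b_unit
  R_out <- (params$R_ref / params$h) * (net$d_out / params$d_ref)^(-params$k)
  pass <- function(Qabs) {
    # one linearized network solve at frozen |Q|
    Reff <- net$a + b * Qabs
    Rsub <- numeric(n)
    for (i in rev_order) {
      kids <- net$children[[i]]
      Rsub[i] <- Reff[i] +
        if (length(kids)) 1 / sum(1 / Rsub[kids]) else R_out[i]
    }
    Q <- numeric(n)
    P_prox <- numeric(n)
    P_dist <- numeric(n)
    for (i in order) {
      p <- net$parent_idx[i]
      P_prox[i] <- if (is.na(p)) params$P_a else P_dist[p]
      Q[i] <- P_prox[i] / Rsub[i]
      P_dist[i] <- P_prox[i] - Reff[i] * Q[i]
    }
    list(Q = Q, P_prox = P_prox, P_dist = P_dist, Reff = Reff)
  }
  Q <- pass(rep(0, n))$Q         # linear (b = 0) initialization
  residual <- Inf
  iter <- 0L
  if (any(b > 0)) {
    repeat {
      iter <- iter + 1L
      sol <- pass(abs(Q))
      residual <- max(abs(sol$Q - Q) / pmax(abs(sol$Q), 1e-300))
      Q_new <- (1 - damping) * Q + damping * sol$Q
      Q <- Q_new
      if (residual < tol) break
      if (iter >= max_iter)
        stop(sprintf("flow solver did not converge in %d iterations (residual %.3e)",
                     max_iter, residual), call. = FALSE)
    }
  } else residual <- 0
  final <- pass(abs(Q))
  list(Q = final$Q, P_prox = final$P_prox, P_dist = final$P_dist,
       b = b, iterations = iter, residual = residual)
}

#' Solve steady hyperemic flow on a vessel tree
#'
#' Damped successive substitution: the quadratic expansion term `b*Q*|Q|` is
#' folded into an effective linear resistance at the previous flow iterate
#' and the resulting resistor tree is solved exactly (bottom-up equivalent
#' resistances, top-down flows); iteration stops when the maximum relative
#' flow change falls below `tol`.  The ostium is held at `P_a`; each outlet
#' drains through its allocated resistance to zero venous pressure.
#'
#' @param tree A `coro_tree` (lesions annotated on it are applied).
#' @param params A [boundary_params()].
#' @param blood A [blood_model()].
#' @param tol Convergence tolerance on the relative flow change.
#' @param max_iter Maximum fixed-point iterations.
#' @param profile Narrowing profile for lesion application.
#' @return An object of class `flow_solution`: `node_pressures` (mmHg; node
#'   `"ostium"` plus one distal node per segment), `segment_flows` (mL/s),
#'   `iterations`, `residual`, and per-segment pressure profiles for
#'   interpolation.
#' @examples
#' tube <- build_tree(data.frame(id = "v", parent = NA, length = 40,
#'                               prox_diameter = 3, dist_diameter = 3))
#' sol <- solve_steady_flow(tube, boundary_params())
#' sol$segment_flows
#' @export
solve_steady_flow <- function(tree, params = boundary_params(),
                              blood = blood_model(), tol = 1e-8,
                              max_iter = 200, profile = "cosine") {
  net <- if (inherits(tree, "coro_network")) tree
         else compile_network(tree, blood, profile)
  sol <- solve_network(net, params, tol, max_iter)
  ids <- net$ids
  node_pressures <- c(ostium = params$P_a, stats::setNames(sol$P_dist, ids))
  segment_flows <- stats::setNames(sol$Q, ids)
  # per-segment pressure profiles: viscous drop accumulates along the arc,
  # each expansion loss is booked at its lesion throat
  profiles <- vector("list", net$n)
  names(profiles) <- ids
  for (i in seq_len(net$n)) {
    seg <- net$tree$segments[[i]]
    p <- sol$P_prox[i] - sol$Q[i] * net$a_cum[[i]]
    if (length(net$throats[[i]])) {
      for (j in seq_along(net$throats[[i]])) {
        drop_j <- params$K_t * net$b_parts[[i]][j] * sol$Q[i] * abs(sol$Q[i])
        p <- p - drop_j * (seg$arc >= net$throats[[i]][j] - 1e-12)
      }
    }
    profiles[[i]] <- list(arc = seg$arc, pressure = p)
  }
  structure(
    list(node_pressures = node_pressures, segment_flows = segment_flows,
         iterations = sol$iterations, residual = sol$residual,
         converged = TRUE, P_a = params$P_a, profiles = profiles,
         network = net),
    class = "flow_solution")
}

#' FFR at every node of a solved tree
#'
#' FFR(node) = P(node) / P_a.  Refuses unconverged solutions.
#'
#' @param solution A [solve_steady_flow()] result.
#' @return Named numeric vector of FFR values in (0, 1].
#' @export
ffr_field <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  if (!isTRUE(solution$converged))
    stop("solution is not converged; refusing to derive FFR", call. = FALSE)
  solution$node_pressures / solution$P_a
}

#' @keywords internal
ffr_at_arc <- function(solution, segment_id, s) {
  prof <- solution$profiles[[segment_id]]
  if (is.null(prof))
    stop(sprintf("segment '%s' not in solution", segment_id), call. = FALSE)
  stats::approx(prof$arc, prof$pressure, xout = s)$y / solution$P_a
}

#' Measure CT-FFR distal to a lesion
#'
#' Interpolates the FFR 2-3 cm (default offset 25 mm) distal to the lesion,
#' following the lesion's segment path; at a bifurcation the branch with the
#' larger distal reference diameter is taken.  If the probe location exceeds
#' the terminal segment the value at the terminal node is returned with the
#' `clipped` flag set.
#'
#' @param solution A [solve_steady_flow()] result on the lesion's tree.
#' @param les The [lesion()] (must lie on a segment of the solved tree).
#' @param offset Distance distal to the lesion end, mm.
#' @return A list of class `ffr_measurement`: `value` in (0, 1],
#'   `segment_id`, `arc_location` (mm on that segment), `clipped`.
#' @export
measure_ffr <- function(solution, les, offset = 25) {
  stopifnot(inherits(solution, "flow_solution"))
  net <- solution$network
  i <- match(les$segment_id, net$ids)
  if (is.na(i))
    stop(sprintf("lesion segment '%s' is not on the solved tree", les$segment_id),
         call. = FALSE)
  target <- les$start + les$length + offset
  clipped <- FALSE
  repeat {
    seg <- net$tree$segments[[i]]
    L <- segment_length(seg)
    if (target <= L + 1e-9) break
    kids <- net$children[[i]]
    if (!length(kids)) { target <- L; clipped <- TRUE; break }
    d_dist <- vapply(kids, function(j) {
      s <- net$tree$segments[[j]]
      s$r_ref[length(s$r_ref)]
    }, numeric(1))
    target <- target - L
    i <- kids[which.max(d_dist)]
  }
  value <- ffr_at_arc(solution, net$ids[i], min(target, segment_length(net$tree$segments[[i]])))
  structure(list(value = value, segment_id = net$ids[i],
                 arc_location = target, clipped = clipped),
            class = "ffr_measurement")
}

#' Export a flow solution as tables
#'
#' @param solution A `flow_solution`.
#' @return A list of two data.frames: `nodes` (node_id, arc_mm,
#'   pressure_mmHg, ffr) and `flows` (segment_id, flow_mL_s).
#' @export
solution_tables <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  net <- solution$network
  ffr <- ffr_field(solution)
  arc <- c(0, vapply(net$tree$segments, segment_length, numeric(1)))
  nodes <- data.frame(node_id = names(solution$node_pressures),
                      arc_mm = unname(arc),
                      pressure_mmHg = unname(solution$node_pressures),
                      ffr = unname(ffr))
  flows <- data.frame(segment_id = names(solution$segment_flows),
                      flow_mL_s = unname(solution$segment_flows))
  rownames(nodes) <- rownames(flows) <- NULL
  list(nodes = nodes, flows = flows)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d segments, %d iteration(s), residual %.2e\n",
              length(x$segment_flows), x$iterations, x$residual))
  cat(sprintf("  ostium %.1f mmHg; min FFR %.4f\n", x$P_a,
              min(x$node_pressures / x$P_a)))
  invisible(x)
}

#' @export
print.ffr_measurement <- function(x, ...) {
  cat(sprintf("CT-FFR %.4f at %.1f mm on segment '%s'%s\n", x$value,
              x$arc_location, x$segment_id, if (x$clipped) " (clipped)" else ""))
  invisible(x)
}
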