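# Independent oracles and fixture builders.  Everything here recomputes
# quantities by a route different from the package implementation.

# Closed-form Poiseuille coefficient of a uniform tube, mmHg.s/mL.
poiseuille_closed_form <- function(mu, L_mm, d_mm) {
  L <- L_mm * 1e-3
  d <- d_mm * 1e-3
  (128 * mu * L / (pi * d^4)) * 1e-6 / 133.322
}

# Dense nodal-conductance solve of a linear resistor tree: one unknown
# pressure per segment distal node, ostium fixed at P_a, outlets drain to
# ground through their resistance.  Independent of the package's
# tree-reduction solver.
linear_network_oracle <- function(tree, params) {
  segs <- tree$segments
  ids <- names(segs)
  n <- length(ids)
  a <- vapply(segs, ctffr::poiseuille_coefficient, numeric(1))
  R_out <- ctffr::assign_outlet_resistances(tree, params)
  G <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in seq_len(n)) {
    g <- 1 / a[i]
    pid <- segs[[i]]$parent_id
    G[i, i] <- G[i, i] + g
    if (is.na(pid)) {
      rhs[i] <- rhs[i] + g * params$P_a
    } else {
      j <- match(pid, ids)
      G[i, j] <- G[i, j] - g
      G[j, i] <- G[j, i] - g
      G[j, j] <- G[j, j] + g
    }
    if (segs[[i]]$is_outlet)
      G[i, i] <- G[i, i] + 1 / R_out[[ids[i]]]
  }
  p <- solve(G, rhs)
  q <- vapply(seq_len(n), function(i) {
    pid <- segs[[i]]$parent_id
    p_up <- if (is.na(pid)) params$P_a else p[match(pid, ids)]
    (p_up - p[i]) / a[i]
  }, numeric(1))
  list(node_pressures = stats::setNames(p, ids),
       segment_flows = stats::setNames(q, ids))
}

# All-pairs concordance AUC, ties 1/2; scores oriented lower = diseased.
auc_brute_force <- function(scores, ischemic) {
  x <- scores[as.logical(ischemic)]
  y <- scores[!as.logical(ischemic)]
  total <- 0
  for (xi in x) for (yj in y)
    total <- total + (yj > xi) + 0.5 * (yj == xi)
  total / (length(x) * length(y))
}

# Mann-Whitney U of x over y by pair enumeration.
u_brute_force <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
fisher_brute_force <- function(tab) {
  m <- rowSums(tab)[1]; n <- rowSums(tab)[2]; k <- colSums(tab)[1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact binomial p at 1/2 by direct summation.
binom_two_sided_brute <- function(x, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Single uniform tube tree fixture.
uniform_tube <- function(length = 40, d = 3, id = "v") {
  build_tree(data.frame(id = id, parent = NA, length = length,
                        prox_diameter = d, dist_diameter = d,
                        stringsAsFactors = FALSE))
}

# Symmetric bifurcation fixture.
symmetric_bifurcation <- function() {
  build_tree(data.frame(
    id = c("root", "L", "R"), parent = c(NA, "root", "root"),
    length = c(20, 30, 30), prox_diameter = c(3.5, 2.8, 2.8),
    dist_diameter = c(3.4, 2.2, 2.2), stringsAsFactors = FALSE))
}

# Random tree via the package generator under a local seed.
seeded_random_tree <- function(n_segments, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  random_tree(n_segments)
}

# Table-3 per-vessel confusion matrices reconstructed from printed fractions.
table3_ctffr_cm <- function() confusion_counts(tp = 152, fp = 24, tn = 173, fn = 17)
table3_cta_cm <- function() confusion_counts(tp = 151, fp = 127, tn = 70, fn = 18)

# Cohort data.frame realizing given stratum/classification counts.
cohort_from_strata <- function(low_fn = 7, low_tp = 112, gray_fn = 10,
                               gray_tp = 40, high_tn = 176, high_fp = 21) {
  measured <- c(rep(0.70, low_fn + low_tp), rep(0.78, gray_fn + gray_tp),
                rep(0.90, high_tn + high_fp))
  ct <- c(rep(0.85, low_fn), rep(0.70, low_tp),
          rep(0.85, gray_fn), rep(0.70, gray_tp),
          rep(0.90, high_tn), rep(0.75, high_fp))
  data.frame(measured_ffr = measured, ct_ffr = ct,
             cta_percent_stenosis = 50)
}
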