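test_that("segment construction tapers linearly and validates inputs", {
  seg <- make_segment(10, 3.0, 3.0, n_samples = 5)
  expect_equal(2 * seg$r_ref, rep(3.0, 5))
  expect_equal(seg$r_lumen, seg$r_ref)

  seg <- make_segment(10, 3.0, 2.0, n_samples = 3)
  expect_equal(2 * seg$r_ref[2], 2.5)

  # taper evaluated against an independent linear-interpolation oracle
  seg <- make_segment(10, 3.0, 2.4, n_samples = 101)
  oracle <- approx(c(0, 10), c(3.0, 2.4) / 2, xout = 2.5)$y
  expect_equal(seg$r_ref[seg$arc == 2.5], oracle, tolerance = 1e-12)

  expect_error(make_segment(-1, 3, 3), "positive")
  expect_error(make_segment(10, 0, 3), "positive")
  expect_error(make_segment(10, 3, 3, n_samples = 1), "at least 2")
})

test_that("stenosis narrows the throat to the prescribed diameter", {
  tube <- make_segment(30, 3, 3, id = "s")
  sten <- apply_stenosis(tube, lesion("s", 10, 10, 50))
  expect_equal(min(2 * sten$r_lumen), 1.5, tolerance = 1e-12)
  # area stenosis at the throat: 1 - (1 - 0.5)^2 = 75%
  i <- which.min(sten$r_lumen)
  expect_equal(1 - (sten$r_lumen[i] / sten$r_ref[i])^2, 0.75, tolerance = 1e-12)

  # degree 0 leaves the lumen unchanged
  same <- apply_stenosis(tube, lesion("s", 10, 10, 0))
  expect_equal(same$r_lumen, same$r_ref)

  expect_error(apply_stenosis(tube, lesion("s", 25, 10, 50)), "within")
  expect_error(lesion("s", 10, 10, 100), "\\[0, 100\\)")
  expect_error(lesion("s", 10, 0, 50), "positive")
})

test_that("stenosis never exceeds reference or reaches zero for degree < 100", {
  tube <- make_segment(30, 3, 2.2, id = "s")
  for (deg in c(10, 50, 90, 99.9)) {
    sten <- apply_stenosis(tube, lesion("s", 5, 20, deg))
    expect_true(all(sten$r_lumen > 0))
    expect_true(all(sten$r_lumen <= sten$r_ref + 1e-12))
  }
})

test_that("lesion length is the centerline distance over the lesion", {
  tube <- make_segment(40, 3, 3, id = "s")
  les <- lesion("s", 5, 20, 50)
  expect_equal(lesion_length(les, tube), 20)
  # nonuniform spacing: arc accumulation over the lesion matches a
  # cumulative-sum oracle
  seg <- make_segment(40, 3, 2.5, id = "s")
  seg$arc <- sort(c(0, 40, runif(50, 0, 40)))
  seg$r_ref <- seg$r_lumen <- (3 - 0.5 * seg$arc / 40) / 2
  inside <- seg$arc >= 5 & seg$arc <= 25
  expect_equal(sum(diff(seg$arc[inside])),
               max(seg$arc[inside]) - min(seg$arc[inside]))
  expect_error(lesion("s", 5, -3, 50), "positive")
})

test_that("plaque burden matches analytic and refined-quadrature oracles", {
  tube <- make_segment(30, 3, 3, id = "s")
  les <- lesion("s", 5, 20, 0)
  expect_equal(plaque_burden(tube, les)$plaque_burden_pct, 0)

  # uniform 50% diameter narrowing over the whole lesion: 1 - 0.25 = 75%
  rect <- apply_stenosis(tube, les50 <- lesion("s", 5, 20, 50), "rectangular")
  expect_equal(plaque_burden(rect, les50)$plaque_burden_pct, 75, tolerance = 1e-9)
  expect_equal(plaque_burden(rect, les50)$min_lumen_diameter_mm, 1.5,
               tolerance = 1e-12)

  # cosine profile vs trapezoidal oracle at 10x finer sampling
  cosl <- apply_stenosis(tube, les50, "cosine")
  got <- plaque_burden(cosl, les50)$plaque_burden_pct
  s <- seq(5, 25, length.out = 10 * length(cosl$arc))
  r_ref <- 1.5
  w <- sin(pi * (s - 5) / 20)^2
  r_lum <- r_ref * (1 - 0.5 * w)
  trap <- function(y) sum(diff(s) * (y[-1] + y[-length(y)]) / 2)
  oracle <- 100 * trap(pi * (r_ref^2 - r_lum^2)) / trap(rep(pi * r_ref^2, length(s)))
  expect_equal(got, oracle, tolerance = 5e-3)
})

test_that("plaque burden is monotone in stenosis degree", {
  tube <- make_segment(30, 3, 3, id = "s")
  burdens <- sapply(seq(0, 90, by = 10), function(deg) {
    les <- lesion("s", 5, 20, deg)
    plaque_burden(apply_stenosis(tube, les), les)$plaque_burden_pct
  })
  expect_true(all(diff(burdens) >= 0))
})

test_that("tree construction validates topology", {
  one <- build_tree(data.frame(id = "a", parent = NA, length = 30,
                               prox_diameter = 3, dist_diameter = 2.5))
  expect_identical(one$root_id, "a")

  bif <- symmetric_bifurcation()
  expect_identical(bif$segments$L$r_ref, bif$segments$R$r_ref)

  # 3-generation tree: segment count equals a recursive enumeration
  spec <- data.frame(
    id = c("r", "a", "b", "a1", "a2", "b1", "b2"),
    parent = c(NA, "r", "r", "a", "a", "b", "b"),
    length = 20, prox_diameter = c(3.5, 2.8, 2.8, 2.2, 2.2, 2.2, 2.2),
    dist_diameter = c(3.0, 2.4, 2.4, 1.8, 1.8, 1.8, 1.8))
  count_nodes <- function(id) {
    kids <- spec$id[!is.na(spec$parent) & spec$parent == id]
    1 + sum(vapply(kids, count_nodes, numeric(1)))
  }
  expect_equal(length(build_tree(spec)$segments), count_nodes("r"))

  # cyclic spec refused
  expect_error(build_tree(data.frame(
    id = c("a", "b"), parent = c("b", "a"), length = 10,
    prox_diameter = 3, dist_diameter = 3)), "root")
  # disconnected spec refused
  expect_error(build_tree(data.frame(
    id = c("a", "b", "c"), parent = c(NA, "b", "b"), length = 10,
    prox_diameter = 3, dist_diameter = 3)), "root|disconnected")
})

test_that("child radii cannot exceed the parent's distal radius", {
  expect_error(build_tree(data.frame(
    id = c("a", "b"), parent = c(NA, "a"), length = 10,
    prox_diameter = c(3, 4), dist_diameter = c(2.8, 3))),
    "exceeds parent")
})
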