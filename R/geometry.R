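# Vessel-tree data model: centerline arc-length + lumen/reference radius
# samples, branching topology, lesion annotations, plaque-burden metrics.
# Units: mm throughout; arc length measured from each segment's proximal end.

#' Default centerline sampling step (mm)
#'
#' Sub-millimetre resolution so 1-2 mm stenosis throats are resolved.
#' @keywords internal
DEFAULT_STEP_MM <- 0.25

#' Construct a tapered vessel segment
#'
#' Builds one centerline segment with reference (disease-free) radius
#' tapering linearly from the proximal to the distal diameter.  The lumen
#' radius is initialized equal to the reference radius; stenoses are applied
#' afterwards with [apply_stenosis()].
#'
#' @param length Segment length (mm), > 0.
#' @param prox_diameter,dist_diameter Proximal / distal reference lumen
#'   diameters (mm), > 0.
#' @param n_samples Number of centerline samples (>= 2).  Defaults to the
#'   number needed for a step of at most 0.25 mm.
#' @param id Segment identifier (character).
#' @param parent_id Identifier of the parent segment, or `NA` for a root.
#' @param is_outlet Whether the distal end is an outflow boundary.
#' @return An object of class `coro_segment`: a list with `id`, `parent_id`,
#'   `arc` (mm, strictly increasing from 0), `r_lumen`, `r_ref` (mm) and
#'   `is_outlet`.
#' @examples
#' seg <- make_segment(10, 3.0, 2.0, n_samples = 3)
#' 2 * seg$r_ref[2]  # mid-sample diameter, 2.5 mm
#' @export
make_segment <- function(length, prox_diameter, dist_diameter,
                         n_samples = NULL, id = "seg1", parent_id = NA_character_,
                         is_outlet = TRUE) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) || length <= 0)
    stop("`length` must be a single positive number (mm)", call. = FALSE)
  if (prox_diameter <= 0 || dist_diameter <= 0)
    stop("diameters must be positive (mm)", call. = FALSE)
  if (is.null(n_samples))
    n_samples <- max(2L, as.integer(ceiling(length / DEFAULT_STEP_MM)) + 1L)
  if (n_samples < 2L)
    stop("`n_samples` must be at least 2", call. = FALSE)
  arc <- seq(0, length, length.out = n_samples)
  r_ref <- (prox_diameter + (dist_diameter - prox_diameter) * arc / length) / 2
  seg <- structure(
    list(id = as.character(id), parent_id = as.character(parent_id),
         arc = arc, r_lumen = r_ref, r_ref = r_ref,
         is_outlet = isTRUE(is_outlet)),
    class = "coro_segment")
  validate_segment(seg)
  seg
}

#' @keywords internal
validate_segment <- function(seg) {
  stopifnot(inherits(seg, "coro_segment"))
  if (length(seg$arc) < 2L)
    stop("segment needs >= 2 samples", call. = FALSE)
  if (seg$arc[1] != 0 || any(diff(seg$arc) <= 0))
    stop("arc lengths must increase strictly from 0", call. = FALSE)
  if (any(seg$r_lumen <= 0) || any(seg$r_ref <= 0))
    stop("all radii must be positive", call. = FALSE)
  if (any(seg$r_lumen > seg$r_ref + 1e-12))
    stop("lumen radius cannot exceed reference radius", call. = FALSE)
  invisible(seg)
}

#' Segment length (mm)
#' @param seg A `coro_segment`.
#' @keywords internal
segment_length <- function(seg) seg$arc[length(seg$arc)]

#' Annotate a target lesion
#'
#' A lesion is a contiguous narrowing on one segment, described by its
#' arc-length extent and percent diameter stenosis, plus plaque covariates
#' carried through to the trial tables.
#'
#' @param segment_id Identifier of the host segment.
#' @param start Arc-length of the proximal lesion end (mm, from the segment's
#'   proximal end).
#' @param length Lesion length (mm), > 0.
#' @param degree Percent diameter stenosis in `[0, 100)`.
#' @param calcified_volume,noncalcified_volume Plaque component volumes (mm^3).
#' @param calcium_score Dimensionless calcium-burden surrogate (>= 0).
#' @return An object of class `coro_lesion`.
#' @export
lesion <- function(segment_id, start, length, degree,
                   calcified_volume = 0, noncalcified_volume = 0,
                   calcium_score = 0) {
  if (!is.finite(degree) || degree < 0 || degree >= 100)
    stop("`degree` must lie in [0, 100)", call. = FALSE)
  if (!is.finite(length) || length <= 0)
    stop("lesion `length` must be positive", call. = FALSE)
  if (!is.finite(start) || start < 0)
    stop("lesion `start` must be >= 0", call. = FALSE)
  if (calcified_volume < 0 || noncalcified_volume < 0 || calcium_score < 0)
    stop("plaque volumes and calcium score must be >= 0", call. = FALSE)
  structure(
    list(segment_id = as.character(segment_id), start = start, length = length,
         degree = degree, calcified_volume = calcified_volume,
         noncalcified_volume = noncalcified_volume,
         calcium_score = calcium_score),
    class = "coro_lesion")
}

#' @keywords internal
check_lesion_on_segment <- function(seg, les) {
  if (!identical(les$segment_id, seg$id))
    stop(sprintf("lesion targets segment '%s', not '%s'", les$segment_id, seg$id),
         call. = FALSE)
  if (les$start < 0 || les$start + les$length > segment_length(seg) + 1e-9)
    stop("lesion extent [start, start+length] must lie within the segment",
         call. = FALSE)
  invisible(TRUE)
}

#' Narrowing weight profile along a lesion
#'
#' @param t Normalized position in `[0, 1]` along the lesion.
#' @param profile `"cosine"` (C1-smooth cosine-squared bump peaking at the
#'   lesion midpoint) or `"rectangular"` (full narrowing over the whole
#'   extent).
#' @return Weights in `[0, 1]`; 1 at the throat.
#' @keywords internal
narrowing_profile <- function(t, profile = c("cosine", "rectangular")) {
  profile <- match.arg(profile)
  w <- switch(profile,
              cosine = sin(pi * t)^2,
              rectangular = rep(1, length(t)))
  w[t < 0 | t > 1] <- 0
  w
}

#' Apply a stenosis to a segment
#'
#' Reduces the lumen radius inside the lesion extent by a smooth profile so
#' the minimal lumen diameter equals `reference diameter * (1 - degree/100)`
#' at the throat.  The segment is resampled so the lesion ends and the throat
#' fall exactly on samples and the lesion interior is sampled at <= 0.25 mm.
#'
#' @param segment A `coro_segment`.
#' @param les A [lesion()] lying within the segment.
#' @param profile Narrowing shape, `"cosine"` (default) or `"rectangular"`.
#' @return The narrowed `coro_segment`; samples outside the lesion keep their
#'   lumen radius.
#' @examples
#' tube <- make_segment(30, 3, 3, id = "s")
#' sten <- apply_stenosis(tube, lesion("s", 10, 10, 50))
#' min(2 * sten$r_lumen)  # 1.5 mm minimal lumen diameter
#' @export
apply_stenosis <- function(segment, les, profile = c("cosine", "rectangular")) {
  profile <- match.arg(profile)
  validate_segment(segment)
  check_lesion_on_segment(segment, les)
  s0 <- les$start
  s1 <- les$start + les$length
  throat <- (s0 + s1) / 2
  step <- min(DEFAULT_STEP_MM, les$length / 20)
  arc <- sort(unique(c(segment$arc, s0, s1, throat,
                       seq(s0, s1, by = step))))
  arc <- arc[arc >= 0 & arc <= segment_length(segment) + 1e-12]
  r_ref <- stats::approx(segment$arc, segment$r_ref, xout = arc)$y
  r_lum <- stats::approx(segment$arc, segment$r_lumen, xout = arc)$y
  inside <- arc >= s0 - 1e-12 & arc <= s1 + 1e-12
  t <- (arc[inside] - s0) / les$length
  w <- narrowing_profile(t, profile)
  factor <- 1 - (les$degree / 100) * w
  r_lum[inside] <- pmin(r_lum[inside], r_ref[inside] * factor)
  out <- segment
  out$arc <- arc
  out$r_lumen <- r_lum
  out$r_ref <- r_ref
  validate_segment(out)
  out
}

#' Centerline length of a lesion
#'
#' Distance from the proximal to the distal lesion end along the centerline.
#'
#' @inheritParams apply_stenosis
#' @return Length in mm.
#' @export
lesion_length <- function(les, segment) {
  check_lesion_on_segment(segment, les)
  les$length
}

#' Plaque burden and lumen metrics over a lesion
#'
#' Plaque volume is the integral over the lesion of (reference cross-section
#' area - lumen area); total vessel volume is the integral of the reference
#' area.  Plaque burden is their ratio as a percentage.  Trapezoidal
#' quadrature over the segment samples.
#'
#' @inheritParams apply_stenosis
#' @return A list: `plaque_burden_pct`, `plaque_volume_mm3`,
#'   `vessel_volume_mm3`, `min_lumen_area_mm2`, `min_lumen_diameter_mm`.
#' @examples
#' tube <- make_segment(30, 3, 3, id = "s")
#' les <- lesion("s", 5, 20, 50)
#' plaque_burden(apply_stenosis(tube, les, "rectangular"), les)$plaque_burden_pct
#' @export
plaque_burden <- function(segment, les) {
  validate_segment(segment)
  check_lesion_on_segment(segment, les)
  s0 <- les$start
  s1 <- les$start + les$length
  arc <- sort(unique(c(segment$arc[segment$arc > s0 & segment$arc < s1], s0, s1)))
  r_ref <- stats::approx(segment$arc, segment$r_ref, xout = arc)$y
  r_lum <- stats::approx(segment$arc, segment$r_lumen, xout = arc)$y
  a_ref <- pi * r_ref^2
  a_lum <- pi * r_lum^2
  trap <- function(y) sum(diff(arc) * (y[-1] + y[-length(y)]) / 2)
  vol_vessel <- trap(a_ref)
  vol_plaque <- trap(a_ref - a_lum)
  list(plaque_burden_pct = 100 * vol_plaque / vol_vessel,
       plaque_volume_mm3 = vol_plaque,
       vessel_volume_mm3 = vol_vessel,
       min_lumen_area_mm2 = min(a_lum),
       min_lumen_diameter_mm = 2 * min(r_lum))
}

#' Assemble a vessel tree
#'
#' @param segments List of `coro_segment`s whose `parent_id`s describe a
#'   rooted tree (exactly one segment with `NA` parent).
#' @param vessel_label One of `"LAD"`, `"LCX"`, `"RCA"`.
#' @param lesions Optional list of [lesion()]s annotated on the tree.
#' @return An object of class `coro_tree`: `segments` (named list),
#'   `root_id`, `vessel_label`, `lesions`.
#' @export
vessel_tree <- function(segments, vessel_label = c("LAD", "LCX", "RCA"),
                        lesions = list()) {
  vessel_label <- match.arg(vessel_label)
  ids <- vapply(segments, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate segment ids", call. = FALSE)
  names(segments) <- ids
  tree <- structure(
    list(segments = segments, root_id = NA_character_,
         vessel_label = vessel_label, lesions = lesions),
    class = "coro_tree")
  validate_tree(tree)
}

#' @keywords internal
validate_tree <- function(tree, radius_tol = 0.05) {
  segs <- tree$segments
  ids <- names(segs)
  parents <- vapply(segs, `[[`, character(1), "parent_id")
  roots <- ids[is.na(parents)]
  if (length(roots) != 1L)
    stop(sprintf("tree must have exactly one root, found %d", length(roots)),
         call. = FALSE)
  bad <- parents[!is.na(parents) & !(parents %in% ids)]
  if (length(bad))
    stop(sprintf("unknown parent id(s): %s", paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  # reachability from the root guards against cycles among non-roots
  children <- split(ids, factor(parents, levels = ids))
  seen <- character(0)
  frontier <- roots
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- unlist(children[frontier], use.names = FALSE)
  }
  if (length(seen) != length(ids))
    stop("tree is disconnected or cyclic", call. = FALSE)
  for (sid in ids) {
    seg <- segs[[sid]]
    validate_segment(seg)
    pid <- seg$parent_id
    if (!is.na(pid)) {
      r_parent_dist <- segs[[pid]]$r_ref[length(segs[[pid]]$r_ref)]
      if (seg$r_ref[1] > r_parent_dist + radius_tol)
        stop(sprintf("segment '%s' proximal reference radius exceeds parent's distal radius",
                     sid), call. = FALSE)
    }
  }
  for (les in tree$lesions)
    check_lesion_on_segment(segs[[les$segment_id]], les)
  tree$root_id <- roots
  tree
}

#' @keywords internal
tree_children <- function(tree, id) {
  parents <- vapply(tree$segments, `[[`, character(1), "parent_id")
  names(tree$segments)[!is.na(parents) & parents == id]
}

#' Build a vessel tree from a branch table
#'
#' Convenience constructor from a per-branch description.
#'
#' @param branches A data.frame (or list of lists) with columns `id`,
#'   `parent` (`NA` for the root), `length`, `prox_diameter`,
#'   `dist_diameter`, and optional `is_outlet` (default: leaves).
#' @param vessel_label Vessel label for the tree.
#' @param lesions Optional lesion list.
#' @return A `coro_tree`.
#' @examples
#' build_tree(data.frame(id = "root", parent = NA, length = 30,
#'                       prox_diameter = 3, dist_diameter = 2.5))
#' @export
build_tree <- function(branches, vessel_label = "LAD", lesions = list()) {
  branches <- as.data.frame(branches, stringsAsFactors = FALSE)
  need <- c("id", "parent", "length", "prox_diameter", "dist_diameter")
  miss <- setdiff(need, names(branches))
  if (length(miss))
    stop(sprintf("branch table missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  leaves <- !(branches$id %in% branches$parent[!is.na(branches$parent)])
  if (is.null(branches$is_outlet)) branches$is_outlet <- leaves
  segs <- lapply(seq_len(nrow(branches)), function(i) {
    make_segment(branches$length[i], branches$prox_diameter[i],
                 branches$dist_diameter[i],
                 id = branches$id[i],
                 parent_id = if (is.na(branches$parent[i])) NA_character_
                             else as.character(branches$parent[i]),
                 is_outlet = branches$is_outlet[i])
  })
  vessel_tree(segs, vessel_label, lesions)
}

#' Apply all annotated lesions of a tree to its segment geometry
#'
#' @param tree A `coro_tree` whose `lesions` have not yet narrowed the lumen.
#' @param profile Narrowing profile passed to [apply_stenosis()].
#' @return The tree with narrowed segments.
#' @export
apply_lesions <- function(tree, profile = "cosine") {
  for (les in tree$lesions) {
    sid <- les$segment_id
    tree$segments[[sid]] <- apply_stenosis(tree$segments[[sid]], les, profile)
  }
  tree
}

#' @export
print.coro_tree <- function(x, ...) {
  cat(sprintf("<coro_tree> %s: %d segment(s), %d lesion(s), root '%s'\n",
              x$vessel_label, length(x$segments), length(x$lesions), x$root_id))
  invisible(x)
}

#' @export
print.coro_segment <- function(x, ...) {
  cat(sprintf("<coro_segment> '%s': %.1f mm, %d samples, ref diameter %.2f -> %.2f mm%s\n",
              x$id, segment_length(x), length(x$arc),
              2 * x$r_ref[1], 2 * x$r_ref[length(x$r_ref)],
              if (x$is_outlet) ", outlet" else ""))
  invisible(x)
}
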