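# Measurement operators over 3D centerlines.  A centerline is an n x 3
# numeric matrix of points in mm, ordered along the structure; operators
# consume it as given (no resampling or smoothing).

.as_centerline <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 3) stop("centerline must be an n x 3 matrix")
  if (nrow(p) < 8) stop("centerline needs at least 8 points")
  storage.mode(p) <- "double"
  if (anyNA(p)) stop("centerline contains missing coordinates")
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive centerline points must be distinct")
  p
}

#' Total-least-squares plane fit to a centerline
#'
#' Fits the plane minimizing the sum of squared orthogonal distances from
#' the points (the smallest principal component of the centred coordinates).
#' This definition is deterministic and invariant under rigid motion, unlike
#' a plane oriented by eye to the field of view.
#'
#' @param points n x 3 matrix of points (mm).
#' @return List of class \code{plane_fit}: \code{normal} (unit 3-vector),
#'   \code{centroid}, \code{rms_residual_mm}, and the in-plane principal
#'   axes \code{axes} (3 x 2).
#' @export
fit_plane <- function(points) {
  p <- .as_centerline(points)
  ctr <- colMeans(p)
  x <- sweep(p, 2, ctr)
  sv <- svd(x)
  # collinear (or coincident) points leave the plane normal undetermined
  if (sv$d[2] < max(sv$d[1], 1) * 1e-9)
    stop("points are collinear; plane undefined")
  n <- sv$v[, 3]
  res <- sqrt(mean((x %*% n)^2))
  structure(list(normal = n, centroid = ctr, rms_residual_mm = res,
                 axes = sv$v[, 1:2, drop = FALSE]),
            class = "plane_fit")
}

#' In-plane extents (width and height) of a canal arc
#'
#' Projects the centerline into the fitted plane and measures its extent
#' along the two in-plane principal axes: width along the major axis,
#' height along the minor axis.  The anatomical anchoring of the original
#' protocol (a chord through the vestibular openings) is replaced by
#' principal axes, which coincide with it for near-elliptical arcs.
#'
#' @param points n x 3 centerline matrix.
#' @param plane \code{plane_fit} for the same centerline (default: fitted
#'   here).
#' @return Named numeric vector \code{c(height_mm, width_mm)}.
#' @export
arc_extents <- function(points, plane = fit_plane(points)) {
  p <- .as_centerline(points)
  x <- sweep(p, 2, plane$centroid)
  uv <- x %*% plane$axes
  ext <- apply(uv, 2, function(z) diff(range(z)))
  if (any(ext == 0)) stop("degenerate projection; arc has no in-plane extent")
  c(height_mm = ext[2], width_mm = ext[1])
}

#' Total linear deviation of a centerline from a plane
#'
#' The range (max minus min) of the signed orthogonal distances of the
#' points from the plane.  A symmetric sinusoidal warp of amplitude A thus
#' measures 2A, and a one-sided bump of height A measures about A; the
#' range is the only statistic that makes the two commensurate.
#'
#' @param points n x 3 centerline matrix.
#' @param plane \code{plane_fit} (default: fitted here).
#' @return Total linear deviation in mm (0 for a planar curve).
#' @export
linear_deviation <- function(points, plane = fit_plane(points)) {
  p <- .as_centerline(points)
  s <- sweep(p, 2, plane$centroid) %*% plane$normal
  diff(range(s))
}

#' Angle between two canal planes
#'
#' Angle between the plane normals after orienting each normal toward the
#' side of its plane containing the reference point (in practice, the
#' labyrinth centroid).  The orientation convention makes obtuse inter-canal
#' angles representable: canal planes arranged around a common vestibule can
#' legitimately meet at more than 90 degrees.
#'
#' @param plane1,plane2 \code{plane_fit} objects.
#' @param reference_point 3-vector toward which both normals are oriented.
#' @return Angle in degrees, in [0, 180].
#' @export
interplane_angle <- function(plane1, plane2, reference_point) {
  orient <- function(pl) {
    s <- sum(pl$normal * (reference_point - pl$centroid))
    if (s < 0) -pl$normal else pl$normal
  }
  n1 <- orient(plane1); n2 <- orient(plane2)
  acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
}

.axis_frame <- function(direction) {
  u <- direction / sqrt(sum(direction^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

.unwrapped_azimuth <- function(points, axis) {
  p <- .as_centerline(points)
  fr <- .axis_frame(axis$direction)
  x <- sweep(p, 2, axis$origin)
  a <- x %*% fr$e1
  b <- x %*% fr$e2
  r <- sqrt(a^2 + b^2)
  if (any(r < 1e-12)) stop("centerline touches the rotation axis; azimuth undefined")
  phi <- atan2(b, a)
  dphi <- diff(phi)
  dphi <- ifelse(dphi > pi, dphi - 2 * pi, ifelse(dphi < -pi, dphi + 2 * pi, dphi))
  list(cum = c(0, cumsum(dphi)), radial = r, height = drop(x %*% fr$u))
}

#' Cochlear coiling in degrees
#'
#' Cumulative unwrapped polar angle of the centerline points about the
#' rotation axis, measured from the azimuth of the first (basal-most) point
#' -- the reference line of the coiling protocol -- to the last point.
#' Reversing the point order changes only the sign, so the magnitude is
#' returned.
#'
#' @param points n x 3 centerline, ordered base to apex.
#' @param axis list with \code{origin} (3-vector on the axis) and
#'   \code{direction} (3-vector along it), e.g. generator truth or the
#'   normal of the basal-turn plane through the spiral centroid.
#' @return Total coiling in degrees.
#' @export
cochlear_coiling <- function(points, axis) {
  uw <- .unwrapped_azimuth(points, axis)
  abs(uw$cum[length(uw$cum)]) * 180 / pi
}

#' Cochlear spire profile: height, basal width, aspect ratio
#'
#' Height is the extent of the spiral along the rotation axis; basal width
#' is the maximal diameter, perpendicular to the axis, across the first 360
#' degrees of the spiral; the aspect ratio (height/width) is the spire shape
#' index, with 0.55 separating flattened from sharp-pointed cochleae.
#'
#' @inheritParams cochlear_coiling
#' @return Named vector \code{c(height_mm, basal_width_mm, aspect_ratio)}.
#'   If the spiral completes less than a full turn the width is measured
#'   over the available arc and a warning is raised.
#' @export
cochlear_profile <- function(points, axis) {
  uw <- .unwrapped_azimuth(points, axis)
  height <- diff(range(uw$height))
  turn1 <- abs(uw$cum) <= 2 * pi + 1e-9
  if (abs(uw$cum[length(uw$cum)]) < 2 * pi - 1e-9)
    warning("spiral completes less than one turn; basal width measured over available arc")
  p <- .as_centerline(points)[turn1, , drop = FALSE]
  fr <- .axis_frame(axis$direction)
  x <- sweep(p, 2, axis$origin)
  uv <- cbind(x %*% fr$e1, x %*% fr$e2)
  width <- max(stats::dist(uv))
  c(height_mm = height, basal_width_mm = width, aspect_ratio = height / width)
}

#' Sagittal labyrinthine index
#'
#' Percentage of the orthogonal span of the posterior semicircular canal arc
#' lying below the plane of the lateral semicircular canal, where "below" is
#' the side away from the supplied dorsal direction.  An index of 0 means
#' the lateral canal plane sits entirely below the posterior arc (the low,
#' plesiomorphic condition); positive values mean the lateral canal divides
#' the posterior arc in anterior view.
#'
#' @param posterior_points n x 3 centerline of the posterior canal.
#' @param lateral_plane \code{plane_fit} of the lateral canal.
#' @param dorsal 3-vector pointing dorsally.
#' @return Index in percent, in [0, 100].
#' @export
sagittal_index <- function(posterior_points, lateral_plane, dorsal) {
  p <- .as_centerline(posterior_points)
  n <- lateral_plane$normal
  if (sum(n * dorsal) < 0) n <- -n   # orient the normal dorsally
  s <- sweep(p, 2, lateral_plane$centroid) %*% n
  lo <- min(s); hi <- max(s)
  if (hi == lo) stop("posterior arc has no span orthogonal to the lateral plane")
  below <- max(0, min(hi, 0) - lo)
  100 * below / (hi - lo)
}

#' Measure a synthetic labyrinth with the geometry operators
#'
#' Convenience wrapper composing \code{\link{fit_plane}},
#' \code{\link{arc_extents}}, \code{\link{linear_deviation}},
#' \code{\link{interplane_angle}}, \code{\link{cochlear_coiling}} and
#' \code{\link{cochlear_profile}} over the bundle returned by
#' \code{\link{generate_labyrinth}}, yielding the same quantities recorded
#' in the bundle's ground truth.
#'
#' @param bundle output of \code{\link{generate_labyrinth}}.
#' @return List with per-canal measured radius/extents/deviation, pairwise
#'   canal plane angles, and cochlear coiling/profile.
#' @export
measure_labyrinth <- function(bundle) {
  planes <- lapply(bundle$canals, function(cl) fit_plane(cl$points))
  ref <- colMeans(do.call(rbind, lapply(bundle$canals, `[[`, "points")))
  canal <- lapply(names(bundle$canals), function(nm) {
    ext <- arc_extents(bundle$canals[[nm]]$points, planes[[nm]])
    list(extents = ext,
         radius_mm = arc_radius(ext["height_mm"], ext["width_mm"]),
         linear_deviation_mm = linear_deviation(bundle$canals[[nm]]$points, planes[[nm]]))
  })
  names(canal) <- names(bundle$canals)
  angles <- c(
    AL = interplane_angle(planes$anterior, planes$lateral, ref),
    AP = interplane_angle(planes$anterior, planes$posterior, ref),
    LP = interplane_angle(planes$lateral, planes$posterior, ref))
  out <- list(canals = canal, angles_deg = angles)
  if (!is.null(bundle$cochlea)) {
    ax <- bundle$cochlea$axis
    out$cochlea <- list(
      coil_deg = cochlear_coiling(bundle$cochlea$points, ax),
      profile = cochlear_profile(bundle$cochlea$points, ax))
  }
  out
}
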