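# Parametric synthetic labyrinths with exact ground truth.  These stand in
# for CT endocast centerlines: every quantity the geometry operators measure
# is known by construction, so operator accuracy can be tested without image
# data.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic semicircular-canal centerline
#'
#' Produces an elliptical arc of given arc radius of curvature and aspect
#' ratio lying in the plane of the given normal, optionally warped out of
#' plane by a single-frequency sinusoid (the simplest model for sigmoidal
#' and curved canal courses) and jittered by isotropic Gaussian noise.
#' The semi-axes are chosen so that \code{(height + width) / 4} equals the
#' requested arc radius exactly.
#'
#' @param arc_radius_mm target arc radius of curvature R (mm).
#' @param aspect height/width ratio of the arc (1 = circle).
#' @param normal plane normal (3-vector, any length).
#' @param center arc centre (3-vector, mm).
#' @param arc_fraction fraction of the full ellipse swept, in (0, 1].
#' @param warp_amplitude_mm amplitude A of the out-of-plane warp
#'   \code{A sin(warp_cycles * t)}; a full circle then has total linear
#'   deviation 2A.
#' @param warp_cycles integer number of warp cycles around the arc.
#' @param n_points number of points (>= 8).
#' @param noise_sd_mm isotropic Gaussian noise sd (mm).
#' @param seed optional RNG seed for the noise; the global RNG state is
#'   restored afterwards.
#' @return List with \code{points} (n x 3), \code{closed}, and \code{truth}
#'   (radius, aspect, extents, unit normal, expected linear deviation).
#' @export
generate_canal <- function(arc_radius_mm, aspect = 1, normal = c(0, 0, 1),
                           center = c(0, 0, 0), arc_fraction = 1,
                           warp_amplitude_mm = 0, warp_cycles = 2,
                           n_points = 256, noise_sd_mm = 0, seed = NULL) {
  stopifnot(arc_radius_mm > 0, aspect > 0, arc_fraction > 0, arc_fraction <= 1,
            warp_amplitude_mm >= 0, noise_sd_mm >= 0)
  if (n_points < 8) stop("n_points must be at least 8")
  fr <- .axis_frame(normal)
  semi_w <- 2 * arc_radius_mm / (1 + aspect)
  semi_h <- aspect * semi_w
  closed <- arc_fraction >= 1
  t <- seq(0, 2 * pi * arc_fraction, length.out = n_points + closed)
  if (closed) t <- t[-length(t)]
  w <- warp_amplitude_mm * sin(warp_cycles * t)
  pts <- outer(semi_w * cos(t), fr$e1) + outer(semi_h * sin(t), fr$e2) +
    outer(w, fr$u)
  pts <- sweep(pts, 2, center, `+`)
  if (noise_sd_mm > 0)
    pts <- pts + .with_seed(seed, matrix(stats::rnorm(3 * nrow(pts), sd = noise_sd_mm),
                                         ncol = 3))
  truth <- list(arc_radius_mm = arc_radius_mm, aspect = aspect,
                height_mm = 2 * semi_h, width_mm = 2 * semi_w,
                normal = fr$u, center = center,
                arc_fraction = arc_fraction,
                expected_linear_deviation_mm = diff(range(w)),
                warp_amplitude_mm = warp_amplitude_mm,
                warp_cycles = warp_cycles, noise_sd_mm = noise_sd_mm)
  list(points = pts, closed = closed, truth = truth)
}

#' Generate a synthetic cochlear spiral centerline
#'
#' Conical helix: the azimuth sweeps \code{coil_degrees} about the axis, the
#' radius shrinks linearly by \code{taper_per_turn_mm} per full turn, and
#' the height increases linearly to \code{height_mm}.
#'
#' The recorded ground-truth basal width is the maximal diameter of the
#' first turn, \code{2 * basal_radius_mm - taper_per_turn_mm / 2} (the chord
#' from the start of the turn to the half-turn point), matching what
#' \code{\link{cochlear_profile}} measures on a tapered spiral.
#'
#' @param coil_degrees total rotation (degrees, > 0).
#' @param basal_radius_mm spiral radius at the base (mm).
#' @param taper_per_turn_mm radius lost per 360 degrees of coil (mm).
#' @param height_mm total height of the spire along the axis (mm).
#' @param n_points number of points (>= 8).
#' @param axis_direction,origin placement of the rotation axis.
#' @param noise_sd_mm isotropic Gaussian noise sd (mm).
#' @param seed optional RNG seed for the noise.
#' @return List with \code{points}, \code{axis} (origin + direction) and
#'   \code{truth} (coil, turns, height, basal width, aspect ratio).
#' @export
generate_cochlea <- function(coil_degrees, basal_radius_mm, taper_per_turn_mm = 0,
                             height_mm = 0, n_points = 512,
                             axis_direction = c(0, 0, 1), origin = c(0, 0, 0),
                             noise_sd_mm = 0, seed = NULL) {
  stopifnot(coil_degrees > 0, basal_radius_mm > 0, taper_per_turn_mm >= 0,
            height_mm >= 0, noise_sd_mm >= 0)
  if (n_points < 8) stop("n_points must be at least 8")
  r_apex <- basal_radius_mm - taper_per_turn_mm * coil_degrees / 360
  if (r_apex <= 0)
    stop("taper drives the spiral radius non-positive before the apex")
  fr <- .axis_frame(axis_direction)
  th <- seq(0, coil_degrees * pi / 180, length.out = n_points)
  r <- basal_radius_mm - taper_per_turn_mm * th / (2 * pi)
  z <- height_mm * th / max(th)
  pts <- outer(r * cos(th), fr$e1) + outer(r * sin(th), fr$e2) + outer(z, fr$u)
  pts <- sweep(pts, 2, origin, `+`)
  if (noise_sd_mm > 0)
    pts <- pts + .with_seed(seed, matrix(stats::rnorm(3 * nrow(pts), sd = noise_sd_mm),
                                         ncol = 3))
  half_turn_r <- if (coil_degrees >= 180) basal_radius_mm - taper_per_turn_mm / 2 else NA_real_
  basal_width <- if (is.na(half_turn_r)) NA_real_ else basal_radius_mm + half_turn_r
  truth <- list(coil_degrees = coil_degrees, turns = coil_degrees / 360,
                height_mm = height_mm, basal_radius_mm = basal_radius_mm,
                basal_width_mm = basal_width,
                aspect_ratio = if (is.na(basal_width)) NA_real_ else height_mm / basal_width,
                taper_per_turn_mm = taper_per_turn_mm, noise_sd_mm = noise_sd_mm)
  list(points = pts, axis = list(origin = origin, direction = fr$u), truth = truth)
}

# Unit vectors with prescribed pairwise angles, via the symmetric square
# root of the Gram matrix; fails if no such triple exists in 3-space.
.vectors_from_angles <- function(angles_deg) {
  ca <- cos(angles_deg * pi / 180)
  G <- matrix(c(1, ca[1], ca[2],
                ca[1], 1, ca[3],
                ca[2], ca[3], 1), 3, 3)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-9)
    stop("no arrangement of three planes realizes angles (",
         paste(angles_deg, collapse = ", "), ")")
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  lapply(1:3, function(i) A[i, ])
}

#' Generate a full synthetic labyrinth bundle
#'
#' Installs three canal arcs with the requested mutual plane angles
#' (anterior-lateral, anterior-posterior, lateral-posterior) around a
#' common centre, plus a cochlear spiral whose basal-turn plane makes the
#' requested angle with the lateral canal plane.  Canal centres are pushed
#' a short distance along their oriented normals so that, seen from the
#' bundle centroid, all normals flip consistently and
#' \code{\link{interplane_angle}} recovers the requested angles.
#'
#' @param angles_deg numeric length 3: the AL, AP and LP plane angles
#'   (degrees).
#' @param canal_radii_mm radii of the anterior, lateral and posterior arcs.
#' @param canal_aspects aspect ratios of the three arcs.
#' @param warp_amplitude_mm,warp_cycles shared out-of-plane warp parameters.
#' @param cochlea list of arguments for \code{\link{generate_cochlea}}, or
#'   \code{NULL} for no cochlea.
#' @param basal_angle_deg angle between the cochlear basal-turn plane and
#'   the lateral canal plane.
#' @param n_points points per canal.
#' @param noise_sd_mm isotropic noise sd applied to every centerline.
#' @param seed RNG seed for the noise.
#' @return List with \code{canals} (named anterior/lateral/posterior, each
#'   a \code{generate_canal} result), \code{cochlea}, and \code{truth}
#'   recording the requested pairwise angles.
#' @export
generate_labyrinth <- function(angles_deg = c(90, 90, 90),
                               canal_radii_mm = c(1.46, 0.88, 1.23),
                               canal_aspects = c(1, 1, 1),
                               warp_amplitude_mm = 0, warp_cycles = 2,
                               cochlea = NULL, basal_angle_deg = 20,
                               n_points = 256, noise_sd_mm = 0, seed = NULL) {
  stopifnot(length(angles_deg) == 3, length(canal_radii_mm) == 3)
  normals <- .vectors_from_angles(angles_deg)
  offset <- 0.25 * mean(canal_radii_mm)
  nm <- c("anterior", "lateral", "posterior")
  canals <- lapply(1:3, function(i)
    generate_canal(canal_radii_mm[i], canal_aspects[i], normal = normals[[i]],
                   center = offset * normals[[i]],
                   warp_amplitude_mm = warp_amplitude_mm,
                   warp_cycles = warp_cycles, n_points = n_points,
                   noise_sd_mm = noise_sd_mm,
                   seed = if (is.null(seed)) NULL else seed + i))
  names(canals) <- nm
  coch <- NULL
  if (!is.null(cochlea)) {
    nL <- normals[[2]]
    perp <- .axis_frame(nL)$e1
    ang <- basal_angle_deg * pi / 180
    w <- cos(ang) * nL + sin(ang) * perp  # cochlear rotation axis
    coch <- do.call(generate_cochlea,
                    c(cochlea, list(axis_direction = w,
                                    origin = -2 * max(canal_radii_mm) * nL,
                                    noise_sd_mm = noise_sd_mm,
                                    seed = if (is.null(seed)) NULL else seed + 4)))
  }
  list(canals = canals, cochlea = coch,
       truth = list(angles_deg = c(AL = angles_deg[1], AP = angles_deg[2],
                                   LP = angles_deg[3]),
                    basal_angle_deg = if (is.null(cochlea)) NA_real_ else basal_angle_deg,
                    canal_radii_mm = canal_radii_mm,
                    canal_aspects = canal_aspects,
                    expected_linear_deviation_mm = 2 * warp_amplitude_mm))
}

#' Named synthetic labyrinth presets
#'
#' Parameter presets spanning the measured range of the study taxa, named
#' after exemplar species: \code{"didelphis"} (moderate opossum-like
#' labyrinth, two-and-a-quarter cochlear turns), \code{"cavia"}
#' (high-spired, heavily coiled guinea-pig-like cochlea) and
#' \code{"tursiops"} (dolphin-like, small canals relative to the cochlea).
#'
#' @param name preset name.
#' @return Argument list for \code{\link{generate_labyrinth}}.
#' @export
labyrinth_preset <- function(name = c("didelphis", "cavia", "tursiops")) {
  name <- match.arg(name)
  switch(name,
    didelphis = list(angles_deg = c(109, 102, 104),
                     canal_radii_mm = c(1.46, 0.88, 1.23),
                     canal_aspects = c(0.97, 0.79, 1.00),
                     cochlea = list(coil_degrees = 791, basal_radius_mm = 1.0,
                                    taper_per_turn_mm = 0.25,
                                    height_mm = 0.62 * (2 - 0.25 / 2)),
                     basal_angle_deg = 19.6),
    cavia = list(angles_deg = c(77.2, 105, 85.5),
                 canal_radii_mm = c(1.88, 1.57, 1.63),
                 canal_aspects = c(0.75, 0.49, 0.99),
                 cochlea = list(coil_degrees = 1457, basal_radius_mm = 1.0,
                                taper_per_turn_mm = 0.18,
                                height_mm = 1.29 * (2 - 0.18 / 2)),
                 basal_angle_deg = 35.1),
    tursiops = list(angles_deg = c(52.2, 84.9, 77.5),
                    canal_radii_mm = c(1.19, 1.36, 0.84),
                    canal_aspects = c(0.95, 0.96, 1.00),
                    cochlea = list(coil_degrees = 661, basal_radius_mm = 1.8,
                                   taper_per_turn_mm = 0.4,
                                   height_mm = 0.47 * (3.6 - 0.4 / 2)),
                    basal_angle_deg = 21.3))
}
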