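#' Semicircular-canal arc radius of curvature
#'
#' The radius of curvature R of a canal arc is half the average of the
#' height and width of the arc, i.e. \code{(height + width) / 4}.  For a
#' circular arc of diameter d both extents equal d and R = d/2.
#'
#' @param arc_height_mm,arc_width_mm in-plane extents of the canal arc (mm);
#'   vectorized.
#' @return Arc radius in mm.
#' @export
arc_radius <- function(arc_height_mm, arc_width_mm) {
  if (any(arc_height_mm < 0, na.rm = TRUE) || any(arc_width_mm < 0, na.rm = TRUE))
    stop("arc extents must be non-negative")
  (arc_height_mm + arc_width_mm) / 4
}

#' Angular deviation of a canal from its plane
#'
#' Converts the total linear deviation of a canal from its best-fit plane
#' into an angle, as the angle subtended at the centre of a circle of the
#' canal's arc radius R by a chord of length equal to the linear deviation:
#' \deqn{\theta = 2 \arcsin(ld / 2R).}
#' A planar canal gives 0 degrees; the limiting chord ld = 2R gives 180.
#'
#' @param linear_deviation_mm total linear deviation (mm); vectorized.
#' @param arc_radius_mm canal arc radius of curvature (mm).
#' @return Angular deviation in degrees, in [0, 180].
#' @export
angular_deviation <- function(linear_deviation_mm, arc_radius_mm) {
  if (any(arc_radius_mm <= 0, na.rm = TRUE)) stop("arc radius must be positive")
  if (any(linear_deviation_mm < 0, na.rm = TRUE)) stop("linear deviation must be non-negative")
  ratio <- linear_deviation_mm / (2 * arc_radius_mm)
  if (any(ratio > 1 + 1e-12, na.rm = TRUE))
    stop("linear deviation exceeds the canal arc diameter; angle undefined")
  2 * asin(pmin(ratio, 1)) * 180 / pi
}

#' Canal deviation ratio and substantiality
#'
#' The ratio of the total linear deviation of a canal from its plane to the
#' cross-sectional lumen diameter at the canal midpoint.  A deviation at
#' least as large as the lumen diameter (ratio >= 1) is classified as
#' substantial; the threshold is descriptive, not physiological.
#'
#' @param linear_deviation_mm total linear deviation (mm); vectorized.
#' @param lumen_diameter_mm midpoint cross-sectional diameter (mm).
#' @return Data frame with columns \code{ratio} and \code{substantial}.
#' @export
deviation_ratio <- function(linear_deviation_mm, lumen_diameter_mm) {
  if (any(lumen_diameter_mm <= 0, na.rm = TRUE)) stop("lumen diameter must be positive")
  if (any(linear_deviation_mm < 0, na.rm = TRUE)) stop("linear deviation must be non-negative")
  r <- linear_deviation_mm / lumen_diameter_mm
  data.frame(ratio = r, substantial = r >= 1)
}

#' Slender-length to arc-radius ratio
#'
#' Length of the slender (unampullated) portion of a semicircular canal over
#' its arc radius of curvature.  For a full circular canal of radius R the
#' ratio approaches 2*pi.
#'
#' @param slender_length_mm slender-portion length (mm); vectorized.
#' @param arc_radius_mm arc radius of curvature (mm).
#' @return Dimensionless ratio.
#' @export
slender_ratio <- function(slender_length_mm, arc_radius_mm) {
  if (any(arc_radius_mm <= 0, na.rm = TRUE)) stop("arc radius must be positive")
  slender_length_mm / arc_radius_mm
}

#' Number of cochlear turns
#'
#' @param coil_degrees total degrees of rotation completed by the cochlear
#'   spiral; vectorized.
#' @return Number of turns, \code{coil_degrees / 360}.
#' @export
cochlear_turns <- function(coil_degrees) {
  if (any(coil_degrees < 0, na.rm = TRUE)) stop("coiling must be non-negative")
  coil_degrees / 360
}

#' Volumetric contributions of cochlea and vestibular apparatus
#'
#' Percent of the total labyrinth volume contributed by the cochlear canal;
#' the vestibular contribution (vestibule plus semicircular canals) is its
#' complement, so the two always sum to exactly 100.
#'
#' @param cochlea_volume_mm3,labyrinth_volume_mm3 compartment volumes (mm^3);
#'   vectorized.
#' @return Data frame with columns \code{cochlear_pct} and
#'   \code{vestibular_pct}.
#' @export
volumetric_contributions <- function(cochlea_volume_mm3, labyrinth_volume_mm3) {
  if (any(labyrinth_volume_mm3 <= 0, na.rm = TRUE)) stop("labyrinth volume must be positive")
  if (any(cochlea_volume_mm3 < 0, na.rm = TRUE)) stop("cochlear volume must be non-negative")
  if (any(cochlea_volume_mm3 > labyrinth_volume_mm3, na.rm = TRUE))
    stop("cochlear volume cannot exceed labyrinth volume")
  cp <- 100 * cochlea_volume_mm3 / labyrinth_volume_mm3
  data.frame(cochlear_pct = cp, vestibular_pct = 100 - cp)
}

#' Body-mass-normalized mean canal radius
#'
#' Mean of the three semicircular-canal arc radii divided by body mass and
#' multiplied by 100, the size normalization used when relating canal size
#' to locomotor agility.  Missing mass propagates to a missing ratio.
#'
#' @param mean_arc_radius_mm arithmetic mean of the anterior, lateral and
#'   posterior arc radii (mm); vectorized.
#' @param body_mass_g body mass in grams.
#' @return 100 * radius / mass; \code{NA} where mass is missing.
#' @export
normalized_radius <- function(mean_arc_radius_mm, body_mass_g) {
  if (any(body_mass_g <= 0, na.rm = TRUE)) stop("body mass must be positive")
  ifelse(is.na(body_mass_g), NA_real_, 100 * mean_arc_radius_mm / body_mass_g)
}

.bin_coil <- function(deg) {
  ifelse(is.na(deg), NA_character_,
    ifelse(deg <= 720, "1-2 turns", ifelse(deg <= 1080, "2-3 turns", ">3 turns")))
}
.bin_contribution <- function(pct) {
  ifelse(is.na(pct), NA_character_,
    ifelse(pct <= 50, "<=50%", ifelse(pct <= 75, "51-75%", ">75%")))
}

#' Discrete labyrinth characters of a taxon
#'
#' Derives the six discrete characters traced over the phylogeny from a row
#' of the measurement table:
#' \enumerate{
#'   \item entry of the posterior limb of the lateral semicircular canal
#'     (secondary common crus / posterior ampulla / vestibule), taken from
#'     the fixture annotation;
#'   \item position of the lateral canal plane relative to the posterior
#'     canal: \code{high} iff the sagittal labyrinthine index exceeds 0;
#'   \item largest canal arc radius of curvature (ties are reported as a
#'     slash-joined polymorphic state, never silently broken);
#'   \item cochlear spire shape: \code{high} iff the aspect ratio exceeds
#'     0.55 (0.55 itself is a flattened, low spire);
#'   \item cochlear coiling binned as 1-2 turns (<= 720 deg), 2-3 turns
#'     (720-1080 deg], or over 3 turns (> 1080 deg);
#'   \item cochlear volumetric contribution binned at 50 and 75 percent.
#' }
#'
#' @param record one-row data frame (or list) with the measurement columns
#'   of \code{\link{load_measurements}}.
#' @return Named character vector with elements \code{c1_lsc_entry},
#'   \code{c2_lsc_position}, \code{c3_largest_canal}, \code{c4_cochlea_shape},
#'   \code{c5_coil_bin}, \code{c6_cochlea_contribution_bin}; missing inputs
#'   give \code{NA} states.
#' @export
classify_characters <- function(record) {
  rr <- as.list(record)
  c1 <- if (is.null(rr$lsc_entry) || is.na(rr$lsc_entry)) NA_character_ else rr$lsc_entry
  c2 <- if (is.na(rr$sagittal_index_pct)) NA_character_ else
    if (rr$sagittal_index_pct > 0) "high" else "low"
  radii <- c(anterior = rr$ant_radius_mm, lateral = rr$lat_radius_mm,
             posterior = rr$post_radius_mm)
  c3 <- if (anyNA(radii)) NA_character_ else {
    top <- names(radii)[radii == max(radii)]
    paste(top, collapse = "/")
  }
  c4 <- if (is.na(rr$cochlea_aspect_ratio)) NA_character_ else
    if (rr$cochlea_aspect_ratio > 0.55) "high" else "low"
  c5 <- .bin_coil(rr$cochlea_coil_deg)
  c6 <- if (is.na(rr$cochlea_volume_mm3) || is.na(rr$labyrinth_volume_mm3)) NA_character_ else
    .bin_contribution(100 * rr$cochlea_volume_mm3 / rr$labyrinth_volume_mm3)
  c(c1_lsc_entry = c1, c2_lsc_position = c2, c3_largest_canal = c3,
    c4_cochlea_shape = c4, c5_coil_bin = c5, c6_cochlea_contribution_bin = c6)
}

#' Discrete character matrix for a measurement table
#'
#' Applies \code{\link{classify_characters}} to every taxon.
#'
#' @param measurements data frame from \code{\link{load_measurements}}.
#' @return Data frame with \code{taxon_id} and the six character columns.
#' @export
character_matrix <- function(measurements) {
  out <- t(vapply(seq_len(nrow(measurements)),
                  function(i) classify_characters(measurements[i, ]),
                  character(6)))
  data.frame(taxon_id = measurements$taxon_id, out, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Derived morphometric index table
#'
#' Computes, for every taxon, the derived quantities used throughout the
#' comparative analysis: cochlear turn count, cochlear/vestibular volume
#' contributions, per-canal slender-length/radius ratios, per-canal
#' deviation ratios with substantiality flags, recomputed angular
#' deviations, and the body-mass-normalized mean canal radius.
#'
#' @param measurements data frame from \code{\link{load_measurements}}.
#' @return Data frame with one row per taxon.
#' @export
derive_indices <- function(measurements) {
  m <- measurements
  contrib <- volumetric_contributions(m$cochlea_volume_mm3, m$labyrinth_volume_mm3)
  out <- data.frame(taxon_id = m$taxon_id,
                    turns = cochlear_turns(m$cochlea_coil_deg),
                    cochlear_pct = contrib$cochlear_pct,
                    vestibular_pct = contrib$vestibular_pct,
                    stringsAsFactors = FALSE)
  for (canal in c("ant", "lat", "post")) {
    R <- m[[paste0(canal, "_radius_mm")]]
    ld <- m[[paste0(canal, "_linear_dev_mm")]]
    out[[paste0(canal, "_slender_ratio")]] <- slender_ratio(m[[paste0(canal, "_slender_mm")]], R)
    dr <- deviation_ratio(ld, m[[paste0(canal, "_lumen_mm")]])
    out[[paste0(canal, "_dev_ratio")]] <- dr$ratio
    out[[paste0(canal, "_substantial")]] <- dr$substantial
    out[[paste0(canal, "_angular_dev_deg")]] <- angular_deviation(ld, R)
  }
  mean_r <- rowMeans(m[, c("ant_radius_mm", "lat_radius_mm", "post_radius_mm")])
  out$mean_radius_mm <- mean_r
  out$normalized_radius <- normalized_radius(mean_r, m$body_mass_g)
  out
}
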