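#' Path to a packaged data fixture
#'
#' @param file file name under \code{extdata}, e.g.
#'   \code{"labyrinth_measurements.csv"}.
#' @return Absolute path to the installed fixture.
#' @export
otomorph_fixture <- function(file) {
  p <- system.file("extdata", file, package = "otomorph")
  if (!nzchar(p)) stop("no packaged fixture named '", file, "'")
  p
}

.measurement_cols <- function() {
  c("body_mass_g", "skull_length_mm", "labyrinth_volume_mm3",
    "labyrinth_length_mm", "cochlea_volume_mm3", "cochlea_coil_deg",
    "cochlea_lamina_deg", "cochlea_length_mm", "cochlea_aqueduct_mm",
    "cochlea_aspect_ratio", "cochlea_basal_angle_deg", "vest_aqueduct_mm",
    "stapedial_ratio", "sagittal_index_pct", "angle_AL_deg", "angle_AP_deg",
    "angle_LP_deg",
    paste0(rep(c("ant", "lat", "post"), each = 6), "_",
           rep(c("radius_mm", "slender_mm", "lumen_mm", "linear_dev_mm",
                 "angular_dev_deg", "aspect_ratio"), 3)))
}

#' Load the per-taxon labyrinth measurement table
#'
#' Reads a flat CSV with one row per taxon: taxonomy and ecology annotations
#' (major clade, extant/fossil status, habitat, entry pattern of the lateral
#' semicircular canal) followed by the whole-labyrinth, cochlear, vestibular
#' and per-canal measurement columns.  Empty fields are missing values and
#' are kept as \code{NA}, never coerced to zero.
#'
#' @param path CSV file; defaults to the packaged transcription of the study
#'   dataset (36 therian taxa).
#' @return A data frame with one row per taxon.  Columns ending in
#'   \code{_mm}, \code{_mm3}, \code{_deg}, \code{_g} or \code{_pct} are
#'   numeric; \code{is_average} flags taxa whose measurements are published
#'   per-taxon specimen averages.
#' @export
load_measurements <- function(path = otomorph_fixture("labyrinth_measurements.csv")) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("taxon_id", "major_clade", "status", "habitat", "is_average",
            "lsc_entry", .measurement_cols())
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$taxon_id))
    stop("duplicate taxon_id: ", paste(unique(m$taxon_id[duplicated(m$taxon_id)]), collapse = ", "))
  for (cc in .measurement_cols()) {
    v <- m[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        stop("non-numeric value in column '", cc, "', row(s) ",
             paste(bad, collapse = ", "), ": ", paste(v[bad], collapse = ", "))
      m[[cc]] <- vn
    }
  }
  m$is_average <- as.logical(m$is_average)
  bad_mass <- which(!is.na(m$body_mass_g) & m$body_mass_g <= 0)
  if (length(bad_mass)) stop("non-positive body mass in row(s) ", paste(bad_mass, collapse = ", "))
  bad_vol <- which(!is.na(m$cochlea_volume_mm3) & !is.na(m$labyrinth_volume_mm3) &
                     m$cochlea_volume_mm3 > m$labyrinth_volume_mm3)
  if (length(bad_vol))
    stop("cochlear volume exceeds labyrinth volume for: ",
         paste(m$taxon_id[bad_vol], collapse = ", "))
  m
}

#' Write a measurement table in the fixture CSV dialect
#'
#' Inverse of \code{\link{load_measurements}}: comma-separated, UTF-8,
#' missing values as empty fields, so that a write/read round trip is the
#' identity.
#'
#' @param measurements data frame as returned by \code{load_measurements}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load the composite therian cladogram
#'
#' Reads a Newick tree.  The packaged fixture encodes the composite
#' cladogram used for ancestral-state reconstruction: 36 tips, multifurcating
#' where the source phylogenies are unresolved (base of Placentalia, base of
#' Afrotheria, the ungulate/ferae/bat split, and within Euarchontoglires),
#' with internal nodes labelled A..e for the named clades (A = Theria,
#' B = Eutheria, F = Placentalia, ...).  The fixture carries topology only;
#' absent branch lengths default to 1 on every edge.
#'
#' @param path Newick file.
#' @param taxa optional character vector of known taxon ids; tip labels not
#'   in this set trigger a warning (not an error).
#' @return An \code{ape} \code{phylo} object with \code{edge.length} set.
#' @export
load_tree <- function(path = otomorph_fixture("theria_tree.nwk"), taxa = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file '", path, "'")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(taxa)) {
    unknown <- setdiff(tr$tip.label, taxa)
    if (length(unknown))
      warning("tree tips absent from measurement set: ", paste(unknown, collapse = ", "))
  }
  tr
}

#' Load the intraspecific canal-deviation sample
#'
#' Per-specimen total linear deviations and midpoint lumen diameters of the
#' three semicircular canals for a 12-individual sample of the laboratory
#' opossum \emph{Monodelphis domestica}, together with the published
#' deviation/diameter ratios used to assess intraspecific variation in
#' canal planarity.
#'
#' @param path CSV file; defaults to the packaged fixture.
#' @return Data frame with one row per specimen.
#' @export
load_specimen_deviations <- function(path = otomorph_fixture("monodelphis_deviations.csv")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  stopifnot(!anyDuplicated(d$specimen_id))
  diam <- as.matrix(d[, c("ant_lumen_mm", "lat_lumen_mm", "post_lumen_mm")])
  if (any(diam <= 0, na.rm = TRUE)) stop("non-positive lumen diameter in deviation sample")
  d
}

#' Load the published canal ratio reference table
#'
#' Published normalized canal radii (100 x mean arc radius / body mass) and
#' slender-length/arc-radius ratios, used as the comparison reference for
#' recomputed values.
#'
#' @param path CSV file; defaults to the packaged fixture.
#' @return Data frame with one row per taxon.
#' @export
load_canal_ratio_reference <- function(path = otomorph_fixture("canal_ratios_reference.csv")) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}
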