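#' Pearson correlation on natural-log scale
#'
#' Correlates two positive-valued measurement vectors after natural-log
#' transformation, with pairwise deletion of incomplete pairs.  Significance
#' is the two-tailed p of \code{t = r sqrt((n-2)/(1-r^2))} on n-2 degrees of
#' freedom.
#'
#' @param x_values,y_values paired positive measurements; pairs with any
#'   missing member are dropped.
#' @param alpha significance level (default 0.05).
#' @return List of class \code{log_correlation}: \code{n}, \code{r},
#'   \code{r_squared}, \code{p}, \code{significant}.
#' @export
log_correlation <- function(x_values, y_values, alpha = 0.05) {
  ok <- !is.na(x_values) & !is.na(y_values)
  x <- x_values[ok]; y <- y_values[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (any(x <= 0) || any(y <= 0)) stop("log correlation requires positive values")
  r <- stats::cor(log(x), log(y))
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(n = n, r = r, r_squared = r^2, p = p,
                 significant = p < alpha, alpha = alpha),
            class = "log_correlation")
}

#' Minimal significant correlation coefficient
#'
#' Smallest |r| significant at a two-tailed level alpha with n-2 degrees of
#' freedom: \code{r* = t* / sqrt(n - 2 + t*^2)} where t* is the upper
#' alpha/2 t quantile.
#'
#' @param n number of pairs (>= 3).
#' @param alpha two-tailed significance level.
#' @return Critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (any(n < 3)) stop("n must be at least 3")
  tstar <- stats::qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(n - 2 + tstar^2)
}

.allometry_subset <- function(measurements) {
  m <- measurements
  m[m$status == "extant" & !is.na(m$body_mass_g) & !is.na(m$labyrinth_length_mm), ]
}

#' Allometric regression of labyrinth length on body mass
#'
#' Ordinary least squares of ln(bony labyrinth length, mm) on ln(body mass,
#' g) over the extant taxa with a published body mass.  Fossils and taxa
#' without a usable mass (including the domestic dog, whose breed range
#' makes a species mass meaningless) drop out by having no mass recorded.
#'
#' @param measurements data frame from \code{\link{load_measurements}}.
#' @return List of class \code{allometry_fit}: \code{slope},
#'   \code{intercept}, \code{n}, \code{r_squared}, variable labels, and the
#'   ids of the taxa used.
#' @export
fit_allometry <- function(measurements) {
  m <- .allometry_subset(measurements)
  if (nrow(m) < 3) stop("fewer than 3 taxa with body mass and labyrinth length")
  fit <- stats::lm(log(labyrinth_length_mm) ~ log(body_mass_g), data = m)
  y <- log(m$labyrinth_length_mm)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = nrow(m), r_squared = r2,
                 response = "ln(labyrinth length, mm)",
                 predictor = "ln(body mass, g)",
                 taxa = m$taxon_id),
            class = "allometry_fit")
}

#' Predict body mass from labyrinth length
#'
#' Inverts an allometric fit \code{ln(length) = slope * ln(mass) +
#' intercept} to estimate body mass from a measured labyrinth length, the
#' standard route to body masses for fossil taxa.
#'
#' @param labyrinth_length_mm labyrinth length (mm); vectorized.
#' @param fit an \code{allometry_fit}, or any list with \code{slope} and
#'   \code{intercept} on the natural-log scale (e.g. a published equation).
#' @return Estimated body mass in grams.
#' @export
predict_mass <- function(labyrinth_length_mm, fit) {
  if (any(labyrinth_length_mm <= 0)) stop("length must be positive")
  if (fit$slope == 0) stop("zero slope: mass is unidentified")
  exp((log(labyrinth_length_mm) - fit$intercept) / fit$slope)
}

#' Aquatic versus terrestrial vestibular contribution
#'
#' Compares the vestibular percent contribution to total labyrinth volume
#' between aquatic and terrestrial taxa.  Bats are excluded as the only
#' truly volant mammals; the default terrestrial set is every non-volant,
#' non-aquatic taxon outside the Mesozoic stem eutherians (so fossil
#' terrestrial taxa and the marsupial outgroup are retained).  An F test
#' for variance equality is reported alongside a Welch (unequal-variance)
#' two-tailed t test; the Welch test is the headline comparison.
#'
#' @param measurements data frame from \code{\link{load_measurements}}.
#' @param terrestrial which terrestrial set to use: \code{"default"} as
#'   above, \code{"extant"} drops fossil terrestrial taxa, \code{"placental"}
#'   additionally drops the marsupial outgroup.
#' @param alpha significance level.
#' @return List of class \code{habitat_contrast} with group summaries, the
#'   F test, and the Welch t test (statistic, df, two-tailed p).
#' @export
habitat_contrast <- function(measurements, terrestrial = c("default", "extant", "placental"),
                             alpha = 0.05) {
  terrestrial <- match.arg(terrestrial)
  m <- measurements
  vest <- volumetric_contributions(m$cochlea_volume_mm3, m$labyrinth_volume_mm3)$vestibular_pct
  keep_t <- m$habitat == "terrestrial" & m$major_clade != "Eutheria(stem)"
  if (terrestrial %in% c("extant", "placental")) keep_t <- keep_t & m$status == "extant"
  if (terrestrial == "placental") keep_t <- keep_t & m$major_clade != "Marsupialia"
  keep_a <- m$habitat == "aquatic"
  ter <- vest[keep_t & !is.na(vest)]
  aqu <- vest[keep_a & !is.na(vest)]
  if (length(ter) < 2 || length(aqu) < 2) stop("each group needs at least 2 taxa")
  ft <- stats::var.test(ter, aqu)
  wt <- stats::t.test(ter, aqu, var.equal = FALSE)
  structure(list(
    groups = data.frame(group = c("terrestrial", "aquatic"),
                        n = c(length(ter), length(aqu)),
                        mean = c(mean(ter), mean(aqu)),
                        variance = c(stats::var(ter), stats::var(aqu))),
    terrestrial_taxa = m$taxon_id[keep_t & !is.na(vest)],
    aquatic_taxa = m$taxon_id[keep_a & !is.na(vest)],
    F_statistic = unname(ft$statistic), F_p = ft$p.value,
    t_statistic = unname(wt$statistic), t_df = unname(wt$parameter),
    p = wt$p.value, significant = wt$p.value < alpha, alpha = alpha),
    class = "habitat_contrast")
}

.cor_row <- function(label, x, y, alpha) {
  ct <- tryCatch(log_correlation(x, y, alpha), error = function(e) NULL)
  if (is.null(ct)) return(data.frame(measurement = label, n = NA_integer_,
                                     r = NA_real_, p = NA_real_,
                                     significant = NA))
  data.frame(measurement = label, n = ct$n, r = ct$r, p = ct$p,
             significant = ct$significant)
}

#' Correlation tables of labyrinth dimensions
#'
#' Recomputes the three published correlation panels on the natural-log
#' scale: (1) every measured dimension against body mass, (2) pairwise
#' correlations among the cochlear dimensions, (3) pairwise correlations
#' among semicircular-canal radius, slender length and arc aspect ratio per
#' canal.  Body-mass correlations use only taxa with a recorded mass;
#' within-labyrinth panels use all taxa with both measurements.
#'
#' @param measurements data frame from \code{\link{load_measurements}}.
#' @param alpha significance level.
#' @return List of three data frames: \code{vs_body_mass}, \code{cochlea},
#'   \code{canals}.
#' @export
correlation_tables <- function(measurements, alpha = 0.05) {
  m <- measurements
  bm <- m$body_mass_g
  contrib <- volumetric_contributions(m$cochlea_volume_mm3, m$labyrinth_volume_mm3)
  vars1 <- list(
    "labyrinth volume" = m$labyrinth_volume_mm3,
    "labyrinth length" = m$labyrinth_length_mm,
    "cochlea volume" = m$cochlea_volume_mm3,
    "cochlea percent of total volume" = contrib$cochlear_pct,
    "cochlea canal length" = m$cochlea_length_mm,
    "cochlea aqueduct length" = m$cochlea_aqueduct_mm,
    "cochlea coiling" = m$cochlea_coil_deg,
    "secondary lamina extension" = m$cochlea_lamina_deg,
    "cochlea angle with lateral canal" = m$cochlea_basal_angle_deg,
    "cochlea aspect ratio" = m$cochlea_aspect_ratio,
    "vestibular aqueduct length" = m$vest_aqueduct_mm,
    "stapedial ratio" = m$stapedial_ratio,
    "anterior radius" = m$ant_radius_mm,
    "lateral radius" = m$lat_radius_mm,
    "posterior radius" = m$post_radius_mm,
    "anterior length" = m$ant_slender_mm,
    "lateral length" = m$lat_slender_mm,
    "posterior length" = m$post_slender_mm,
    "anterior diameter" = m$ant_lumen_mm,
    "lateral diameter" = m$lat_lumen_mm,
    "posterior diameter" = m$post_lumen_mm,
    "anterior aspect ratio" = m$ant_aspect_ratio,
    "lateral aspect ratio" = m$lat_aspect_ratio,
    "posterior aspect ratio" = m$post_aspect_ratio)
  t6 <- do.call(rbind, lapply(names(vars1), function(lb) .cor_row(lb, bm, vars1[[lb]], alpha)))

  vars2 <- list(coiling = m$cochlea_coil_deg, volume = m$cochlea_volume_mm3,
                length = m$cochlea_length_mm, aspect_ratio = m$cochlea_aspect_ratio)
  pair_rows <- function(vars) {
    nms <- names(vars)
    do.call(rbind, lapply(seq_along(nms)[-length(nms)], function(i)
      do.call(rbind, lapply((i + 1):length(nms), function(j)
        .cor_row(paste(nms[i], "vs", nms[j]), vars[[i]], vars[[j]], alpha)))))
  }
  t7 <- pair_rows(vars2)

  t8 <- do.call(rbind, lapply(c(ant = "ant", lat = "lat", post = "post"), function(cn) {
    vars <- list(radius = m[[paste0(cn, "_radius_mm")]],
                 length = m[[paste0(cn, "_slender_mm")]],
                 aspect_ratio = m[[paste0(cn, "_aspect_ratio")]])
    cbind(canal = cn, pair_rows(vars))
  }))
  rownames(t8) <- NULL
  list(vs_body_mass = t6, cochlea = t7, canals = t8)
}
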