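#' Run the full comparative labyrinth pipeline
#'
#' Loads the measurement fixtures and cladogram (or user-supplied files),
#' derives all morphometric indices and discrete characters, recomputes the
#' correlation panels, fits the body-mass allometry and predicts masses for
#' the taxa without one, runs the aquatic-versus-terrestrial vestibular
#' contrast, reconstructs ancestral states, and writes every result table
#' as CSV plus a plain-text log recording each taxon excluded from any
#' statistic and the rule that excluded it.
#'
#' @param output_dir directory for the result files (created if needed).
#' @param measurements_path,tree_path input files; default: packaged
#'   fixtures.
#' @param alpha significance level used throughout.
#' @param terrestrial terrestrial grouping variant for
#'   \code{\link{habitat_contrast}}.
#' @return Invisibly, a list with all in-memory results and the paths of
#'   the files written.
#' @export
run_pipeline <- function(output_dir,
                         measurements_path = otomorph_fixture("labyrinth_measurements.csv"),
                         tree_path = otomorph_fixture("theria_tree.nwk"),
                         alpha = 0.05,
                         terrestrial = "default") {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  m <- load_measurements(measurements_path)
  tree <- load_tree(tree_path, taxa = m$taxon_id)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  indices <- derive_indices(m)
  chars <- character_matrix(m)

  cors <- correlation_tables(m, alpha = alpha)
  no_mass <- m$taxon_id[is.na(m$body_mass_g)]
  note("body-mass correlations exclude taxa without recorded mass: ",
       paste(no_mass, collapse = ", "))

  fit <- fit_allometry(m)
  note("allometric regression fitted to ", fit$n,
       " extant taxa with body mass; excluded (no mass or fossil): ",
       paste(setdiff(m$taxon_id, fit$taxa), collapse = ", "))
  need_mass <- m[is.na(m$body_mass_g) & !is.na(m$labyrinth_length_mm), ]
  predictions <- data.frame(taxon_id = need_mass$taxon_id,
                            labyrinth_length_mm = need_mass$labyrinth_length_mm,
                            predicted_mass_g = predict_mass(need_mass$labyrinth_length_mm, fit))

  contrast <- habitat_contrast(m, terrestrial = terrestrial, alpha = alpha)
  note("habitat contrast excludes volant taxa: ",
       paste(m$taxon_id[m$habitat == "volant"], collapse = ", "))
  note("habitat contrast excludes Mesozoic stem eutherians: ",
       paste(m$taxon_id[m$major_clade == "Eutheria(stem)"], collapse = ", "))

  asr <- reconstruct_all(tree, m)

  paths <- c(
    indices = file.path(output_dir, "derived_indices.csv"),
    characters = file.path(output_dir, "discrete_characters.csv"),
    correlations = file.path(output_dir, "correlations_vs_body_mass.csv"),
    correlations_internal = file.path(output_dir, "correlations_within_labyrinth.csv"),
    regression = file.path(output_dir, "allometry_and_mass_predictions.csv"),
    asr = file.path(output_dir, "ancestral_states.csv"))
  utils::write.csv(indices, paths["indices"], row.names = FALSE, na = "")
  utils::write.csv(chars, paths["characters"], row.names = FALSE, na = "")
  utils::write.csv(cors$vs_body_mass, paths["correlations"], row.names = FALSE, na = "")
  utils::write.csv(rbind(cbind(panel = "cochlea", canal = NA, cors$cochlea),
                         cbind(panel = "canals", cors$canals[, c("canal", "measurement",
                                                                 "n", "r", "p", "significant")])),
                   paths["correlations_internal"], row.names = FALSE, na = "")
  reg <- rbind(
    data.frame(taxon_id = "(fit)", labyrinth_length_mm = NA,
               predicted_mass_g = NA, slope = fit$slope, intercept = fit$intercept,
               n = fit$n, r_squared = fit$r_squared),
    cbind(predictions, slope = NA, intercept = NA, n = NA, r_squared = NA))
  utils::write.csv(reg, paths["regression"], row.names = FALSE, na = "")
  utils::write.csv(asr, paths["asr"], row.names = FALSE, na = "")

  summary_path <- file.path(output_dir, "summary.txt")
  con <- file(summary_path, "w")
  writeLines(c(
    "Comparative bony-labyrinth pipeline summary",
    sprintf("taxa: %d (extant %d, fossil %d)", nrow(m),
            sum(m$status == "extant"), sum(m$status == "fossil")),
    sprintf("allometry: ln(length) = %.4f ln(mass) + %.4f (n = %d, r^2 = %.3f)",
            fit$slope, fit$intercept, fit$n, fit$r_squared),
    sprintf("habitat contrast: Welch t = %.3f, df = %.2f, p = %.4g (F-test p = %.4g)",
            contrast$t_statistic, contrast$t_df, contrast$p, contrast$F_p),
    "", "Exclusion log:", log_lines), con)
  close(con)

  invisible(list(measurements = m, tree = tree, indices = indices,
                 characters = chars, correlations = cors, fit = fit,
                 predictions = predictions, contrast = contrast, asr = asr,
                 paths = c(paths, summary = summary_path), log = log_lines))
}

#' Compare recomputed quantities with a reference table
#'
#' Checks a named vector of recomputed values against reference (published)
#' values under per-target tolerance classes: \code{"exact"} targets must
#' match after rounding to the stated number of decimals, \code{"abs"}
#' targets must lie within \code{tolerance} of the reference, and
#' \code{"relative"} targets within \code{tolerance} as a fraction of the
#' reference.
#'
#' @param computed named numeric vector of recomputed values.
#' @param reference data frame with columns \code{target} (matching names
#'   of \code{computed}), \code{value}, \code{class} (exact / abs /
#'   relative), and \code{tolerance} (decimal places for exact, otherwise
#'   the tolerance itself).
#' @return Data frame of per-target verdicts with attribute
#'   \code{"exact_failures"}, the number of failed exact-class targets.
#' @export
compare_to_reference <- function(computed, reference) {
  stopifnot(all(c("target", "value", "class", "tolerance") %in% names(reference)))
  unknown <- setdiff(reference$target, names(computed))
  if (length(unknown)) stop("no computed value for target(s): ",
                            paste(unknown, collapse = ", "))
  verdict <- vapply(seq_len(nrow(reference)), function(i) {
    got <- computed[[reference$target[i]]]
    want <- reference$value[i]
    tol <- reference$tolerance[i]
    switch(reference$class[i],
           exact = isTRUE(round(got, tol) == round(want, tol)),
           abs = isTRUE(abs(got - want) <= tol),
           relative = isTRUE(abs(got - want) <= tol * abs(want)),
           stop("unknown tolerance class: ", reference$class[i]))
  }, logical(1))
  out <- data.frame(target = reference$target, reference = reference$value,
                    computed = unname(computed[reference$target]),
                    class = reference$class, tolerance = reference$tolerance,
                    pass = verdict)
  attr(out, "exact_failures") <- sum(!verdict & reference$class == "exact")
  out
}
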