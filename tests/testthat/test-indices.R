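test_that("arc radius is the quarter-sum of extents and symmetric", {
  expect_equal(arc_radius(2, 2), 1)          # circle of diameter 2
  expect_equal(arc_radius(0, 0), 0)
  h <- runif(20, 0, 5); w <- runif(20, 0, 5)
  expect_equal(arc_radius(h, w), arc_radius(w, h))
  expect_equal(arc_radius(h, w), (h + w) / 4)
  expect_error(arc_radius(-1, 1), "non-negative")
})

test_that("angular deviation is the chord-subtended angle", {
  expect_equal(angular_deviation(0, 1), 0)
  expect_equal(angular_deviation(2, 1), 180)          # limiting chord
  # rhesus anterior canal: ld 1.23 mm on R 2.70 mm prints as 26.4 degrees
  expect_equal(round(angular_deviation(1.23, 2.70), 1), 26.3)
  expect_lt(abs(angular_deviation(1.23, 2.70) - 26.4), 0.5)
  expect_error(angular_deviation(3, 1), "exceeds")
  expect_error(angular_deviation(0.1, 0), "positive")
})

test_that("angular deviation is monotone in deviation and radius", {
  ld <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(angular_deviation(ld, 1)) > 0))
  R <- seq(0.6, 3, by = 0.2)
  expect_true(all(diff(angular_deviation(0.5, R)) < 0))
})

test_that("recomputed angular deviations match the published table", {
  # for extant taxa (published per-taxon averages of Mesozoic taxa excluded),
  # theta = 2 asin(ld / 2R) applied to the printed radii and linear
  # deviations reproduces at least 80% of the printed angles within 0.6 deg
  m <- fixture_measurements()
  ext <- m[!m$is_average, ]
  hits <- 0; n <- 0
  for (canal in c("ant", "lat", "post")) {
    got <- angular_deviation(ext[[paste0(canal, "_linear_dev_mm")]],
                             ext[[paste0(canal, "_radius_mm")]])
    d <- abs(got - ext[[paste0(canal, "_angular_dev_deg")]])
    hits <- hits + sum(d <= 0.6); n <- n + length(d)
  }
  expect_gte(hits / n, 0.8)
})

test_that("deviation ratio and substantiality follow the published rule", {
  r <- deviation_ratio(0.11, 0.19)
  expect_equal(round(r$ratio, 2), 0.58)
  expect_false(r$substantial)
  r2 <- deviation_ratio(0.38, 0.30)      # opossum lateral canal
  expect_equal(round(r2$ratio, 2), 1.27)
  expect_true(r2$substantial)
  expect_equal(deviation_ratio(0, 0.3)$ratio, 0)
  expect_true(deviation_ratio(0.3, 0.3)$substantial)   # ratio of exactly 1 counts
  expect_error(deviation_ratio(0.1, 0), "positive")
})

test_that("intraspecific deviation sample reproduces every published ratio", {
  d <- load_specimen_deviations()
  expect_equal(nrow(d), 12)
  for (canal in c("ant", "lat", "post")) {
    got <- deviation_ratio(d[[paste0(canal, "_linear_dev_mm")]],
                           d[[paste0(canal, "_lumen_mm")]])$ratio
    expect_equal(round(got, 2), d[[paste0(canal, "_ratio")]])
  }
})

test_that("slender ratio behaves as length over radius", {
  expect_equal(round(slender_ratio(8.24, 1.46), 2), 5.64)  # prints 5.63 from unrounded inputs
  expect_equal(slender_ratio(3.3, 3.3), 1)
  expect_error(slender_ratio(1, 0), "positive")
  # a circular arc sweeping fraction f of a circle has length/radius 2*pi*f
  for (f in c(0.4, 0.75, 1)) {
    cn <- generate_canal(1.3, aspect = 1, arc_fraction = f, n_points = 2048)
    arclen <- sum(sqrt(rowSums(diff(cn$points)^2)))
    if (cn$closed) arclen <- arclen + sqrt(sum((cn$points[1, ] - cn$points[nrow(cn$points), ])^2))
    expect_equal(slender_ratio(arclen, 1.3), 2 * pi * f, tolerance = 1e-3)
  }
})

test_that("cochlear turns divide degrees by a full rotation", {
  expect_equal(round(cochlear_turns(791), 2), 2.2)
  expect_equal(cochlear_turns(360), 1)
  expect_equal(round(cochlear_turns(1457), 2), 4.05)
})

test_that("volumetric contributions complement to exactly 100", {
  v <- volumetric_contributions(8.30, 12.1)
  expect_equal(round(v$cochlear_pct), 69)
  expect_equal(v$cochlear_pct + v$vestibular_pct, 100)
  expect_equal(volumetric_contributions(1.39, 2.78)$cochlear_pct, 50)
  expect_equal(volumetric_contributions(0, 5)$vestibular_pct, 100)
  x <- runif(30, 0, 1); V <- runif(30, 1, 10)
  vv <- volumetric_contributions(x, V)
  expect_equal(vv$cochlear_pct + vv$vestibular_pct, rep(100, 30))
  expect_error(volumetric_contributions(3, 2), "exceed")
})

test_that("normalized radius scales mean canal radius by body mass", {
  expect_equal(round(normalized_radius(mean(c(1.46, 0.88, 1.23)), 2800), 2), 0.04)
  expect_equal(round(normalized_radius(mean(c(0.65, 0.48, 0.63)), 6.07), 2), 9.67)
  expect_true(is.na(normalized_radius(1.2, NA)))     # missing mass, never 0
  masses <- 10^(1:6)
  expect_true(all(diff(normalized_radius(1.2, masses)) < 0))
  expect_error(normalized_radius(1, -5), "positive")
})

test_that("discrete character classification follows the published bins", {
  m <- fixture_measurements()
  cavia <- classify_characters(m[m$taxon_id == "Cavia", ])
  expect_equal(unname(cavia["c4_cochlea_shape"]), "high")
  expect_equal(unname(cavia["c5_coil_bin"]), ">3 turns")
  expect_equal(unname(cavia["c6_cochlea_contribution_bin"]), "51-75%")

  did <- classify_characters(m[m$taxon_id == "Didelphis", ])
  expect_equal(unname(did["c2_lsc_position"]), "low")   # sagittal index 0.0
  expect_equal(unname(did["c1_lsc_entry"]), "secondary_common_crus")
  expect_equal(unname(did["c3_largest_canal"]), "anterior")

  # the 0.55 boundary itself is a low, flattened spire
  rec <- m[m$taxon_id == "Didelphis", ]
  rec$cochlea_aspect_ratio <- 0.55
  expect_equal(unname(classify_characters(rec)["c4_cochlea_shape"]), "low")
  # a coil of exactly 720 degrees stays in the 1-2 turn bin
  rec$cochlea_coil_deg <- 720
  expect_equal(unname(classify_characters(rec)["c5_coil_bin"]), "1-2 turns")

  # ties in the largest-canal character are reported as polymorphic
  rec$ant_radius_mm <- 1.5; rec$lat_radius_mm <- 1.5; rec$post_radius_mm <- 1.0
  expect_equal(unname(classify_characters(rec)["c3_largest_canal"]), "anterior/lateral")
})

test_that("derived index table covers every taxon and matches reference ratios", {
  m <- fixture_measurements()
  idx <- derive_indices(m)
  expect_equal(nrow(idx), 36)
  ref <- load_canal_ratio_reference()
  ok <- !is.na(ref$norm_avg)
  # published normalized radii were averaged from rounded per-canal entries,
  # so agreement is approximate
  expect_true(all(abs(idx$normalized_radius[ok] - ref$norm_avg[ok]) <=
                    pmax(0.02, 0.05 * ref$norm_avg[ok])))
  expect_true(all(abs(idx$ant_slender_ratio - ref$lr_ant) <= 0.06))
})
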