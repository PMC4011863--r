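make_records <- function() {
  data.frame(
    species = rep(c("spA", "spB"), c(5, 3)),
    lon = c(-101.5, -101.5, -102.2, -103.0, -104.1,
            -95.0, -95.5, -96.0),
    lat = c(33.1, 33.1, 34.0, 35.2, 36.3, 30.0, 30.5, 31.0),
    elevation = c(500, 500, -5, 1500, 800, 200, NA, 900),
    in_range = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    bio5 = c(38, 38, 36, 35, 33, 34, 35, 33),
    bio6 = c(2, 2, -1, -3, -5, 5, 4, 2),
    bio10 = c(30, 30, 28, 27, 25, 28, 29, 27),
    bio11 = c(8, 8, 5, 3, 1, 12, 11, 9),
    bio12 = c(250, 250, 300, 400, 350, 900, 1000, 1100),
    bio15 = c(80, 80, 75, 60, 55, 30, 28, 35),
    bio16 = c(120, 120, 150, 180, 160, 380, 420, 450),
    stringsAsFactors = FALSE)
}

test_that("locality vetting deduplicates and filters with a full log", {
  rec <- make_records()
  vet <- vet_localities(rec, elevation_min = 0, elevation_max = 1000)
  # spA: one exact duplicate collapsed, elevation -5 and 1500 dropped,
  # in_range = FALSE dropped -> 1 locality; spB keeps all 3 (one without
  # elevation passes with a note)
  expect_equal(sum(vet$kept$species == "spA"), 1)
  expect_equal(sum(vet$kept$species == "spB"), 3)
  expect_setequal(unique(vet$log$reason),
                  c("duplicate_locality", "outside_iucn_range",
                    "elevation_out_of_range", "no_elevation_filter_skipped"))

  # brute-force row-scan oracle over the deduplicated records
  dedup <- rec[!duplicated(paste(rec$species, round(rec$lon, 4),
                                 round(rec$lat, 4))), ]
  keep_manual <- with(dedup, in_range &
                        (is.na(elevation) |
                           (elevation >= 0 & elevation <= 1000)))
  expect_equal(nrow(vet$kept), sum(keep_manual))
})

test_that("vetting is idempotent and errors when a species empties", {
  rec <- make_records()
  vet <- vet_localities(rec, 0, 1000)
  vet2 <- vet_localities(vet$kept, 0, 1000)
  expect_equal(vet2$kept, vet$kept, ignore_attr = TRUE)
  expect_error(vet_localities(rec, 2000, 3000), "spA")
  expect_error(vet_localities(rec, 1000, 0), "finite")
})

test_that("species summaries compute min/max/mean/midpoint per variable", {
  one <- make_records()[6, ]
  s1 <- summarize_species(one)
  expect_equal(s1$bio12_min, s1$bio12_max)
  expect_equal(s1$bio12_mean, s1$bio12_midpoint)
  expect_equal(s1$n_localities, 1)

  two <- make_records()[1:2, ]
  two$bio12 <- c(100, 300)
  two$lat <- c(33, 34)
  s2 <- summarize_species(two)
  expect_equal(s2$bio12_min, 100)
  expect_equal(s2$bio12_max, 300)
  expect_equal(s2$bio12_mean, 200)
  expect_equal(s2$bio12_midpoint, 200)
})

test_that("summaries match a second-pass streaming recomputation", {
  set.seed(9)
  n <- 1000
  bio5 <- rnorm(n, 35, 2)
  rec <- data.frame(species = "big", lon = runif(n, -110, -100),
                    lat = runif(n, 30, 40), bio5 = bio5,
                    bio6 = bio5 - runif(n, 20, 30),
                    bio12 = rlnorm(n, 6, 0.4))
  s <- summarize_species(rec)
  expect_equal(s$bio12_mean, sum(rec$bio12) / n, tolerance = 1e-12)
  expect_equal(s$bio12_min, Reduce(min, rec$bio12))
  expect_equal(s$bio12_midpoint,
               (Reduce(min, rec$bio12) + Reduce(max, rec$bio12)) / 2)
  # permutation invariance
  s_perm <- summarize_species(rec[sample(n), ])
  expect_equal(s_perm, s)
})

test_that("missing variables summarize to NA, never zero", {
  rec <- make_records()[6:8, ]
  rec$bio16 <- NA_real_
  s <- summarize_species(rec)
  expect_true(is.na(s$bio16_mean))
  expect_true(is.na(s$bio16_min))
  expect_false(is.na(s$bio12_mean))
})

test_that("aridity logQ follows its closed form and identities", {
  expect_equal(aridity_logQ(250, 38, 2), log10(250 / (40 * 36)),
               tolerance = 1e-12)
  expect_equal(aridity_logQ(250, 38, 2), -0.7604, tolerance = 1e-4)
  expect_equal(aridity_logQ(500, 38, 2) - aridity_logQ(250, 38, 2),
               log10(2), tolerance = 1e-12)
  expect_equal(aridity_logQ2(500, 25, 5), log10(500 / (30 * 20)),
               tolerance = 1e-12)
  expect_equal(aridity_logQ2(250, 38, 2), aridity_logQ(250, 38, 2))

  # natural-log variant behind the flag
  expect_equal(aridity_logQ(250, 38, 2, base = exp(1)),
               log(250 / (40 * 36)), tolerance = 1e-12)

  expect_error(aridity_logQ(0, 38, 2), "positive")
  expect_error(aridity_logQ(250, 2, 38), "exceed")
  expect_error(aridity_logQ(250, 5, -5), "zero")
  expect_error(aridity_logQ(250, 1, -10), "positive") # negative Q
})

test_that("logQ decreases in tmax for fixed P and tmin", {
  tmaxes <- seq(20, 45, by = 0.5)
  q <- vapply(tmaxes, function(tm) aridity_logQ(400, tm, 3), numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("logQ and logQ2 agree when within-species spread is small", {
  fx <- make_study_fixture(seed = 77)
  loc <- fx$localities
  # shrink within-species temperature dispersion toward the centres
  for (v in c("bio5", "bio6", "bio10", "bio11")) {
    ctr <- stats::ave(loc[[v]], loc$species)
    loc[[v]] <- ctr + 0.05 * (loc[[v]] - ctr)
  }
  loc$bio10 <- loc$bio5 - 0.5
  loc$bio11 <- loc$bio6 + 0.5
  s <- summarize_species(loc)
  expect_lt(stats::median(abs(s$logQ - s$logQ2)), 0.1)
})

test_that("the locality reader applies the declared temperature units", {
  rec <- make_records()[, c("species", "lon", "lat", "bio5", "bio6",
                            "bio12")]
  raw <- rec
  raw$bio5 <- rec$bio5 * 10
  raw$bio6 <- rec$bio6 * 10
  f <- tempfile(fileext = ".csv")
  utils::write.csv(raw, f, row.names = FALSE)
  got <- read_locality_table(f, temperature_units = "worldclim-raw")
  expect_equal(got$bio5, rec$bio5)
  expect_equal(got$bio6, rec$bio6)
  asis <- read_locality_table(f, temperature_units = "celsius")
  expect_equal(asis$bio5, raw$bio5)
})

test_that("record validation enforces coordinate and physical bounds", {
  rec <- make_records()
  bad <- rec; bad$lon[1] <- 200
  expect_error(vet_localities(bad, 0, 1000), "longitude")
  bad <- rec; bad$bio12[1] <- -10
  expect_error(vet_localities(bad, 0, 1000), "precipitation")
  bad <- rec; bad$bio6[1] <- 50
  expect_error(vet_localities(bad, 0, 1000), "bio5 < bio6", fixed = TRUE)
})
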