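test_that("emission-factor lookup uses nearest bins with ties rounding up", {
  g <- expand.grid(month = 1:12, pollutant = "p", vclass = vehicle_classes(),
                   temp_bin = seq(0, 100, 10), speed_bin = c(2.5, seq(5, 75, 5)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$ef <- g$temp_bin + g$speed_bin / 100  # encodes the bin in the value
  tab <- ef_table(g)
  expect_equal(lookup_ef(tab, "p", "LDGV", 8, 50, 45), 50.45)  # exact keys
  expect_equal(lookup_ef(tab, "p", "LDGV", 8, 53, 45), 50.45)  # 53 -> 50
  expect_equal(lookup_ef(tab, "p", "LDGV", 8, 55, 45), 60.45)  # tie rounds up
  expect_equal(lookup_ef(tab, "p", "LDGV", 8, 50, 47), 50.45)  # 47 -> 45
  expect_equal(lookup_ef(tab, "p", "LDGV", 8, 50, 47.5), 50.50)  # tie up
  expect_equal(lookup_ef(tab, "p", "LDGV", 8, 50, 1.0), 50.025)  # clamps to 2.5
  expect_error(lookup_ef(tab, "p", "LDGV", 13, 50, 45), "month")
  expect_error(lookup_ef(tab, "q", "LDGV", 8, 50, 45), "pollutant")
})

test_that("ef_table rejects incomplete axes and negative factors", {
  g <- expand.grid(month = 1:12, pollutant = "p", vclass = vehicle_classes(),
                   temp_bin = seq(0, 100, 10), speed_bin = c(2.5, seq(5, 75, 5)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$ef <- 1
  expect_error(ef_table(g[-1, ]), "incomplete")
  g$ef[5] <- -1
  expect_error(ef_table(g), "negative")
})

test_that("composite EF is the renormalised fraction-weighted class mean", {
  tab <- toy_ef_table(ef_diesel = 0.1, ef_gas = 0.01, pollutant = "p")
  single <- fleet_mix("only", c(LDGV = 1))
  expect_equal(composite_ef(tab, single, "p", 6, 50, 45)$value,
               lookup_ef(tab, "p", "LDGV", 6, 50, 45))
  two <- fleet_mix("two", c(LDGV = 0.9, HDDV = 0.1))
  expect_equal(composite_ef(tab, two, "p", 6, 50, 45)$value, 0.019)
  # degenerate convexity: identical class factors give the common value
  flat <- toy_ef_table(ef_diesel = 0.37, ef_gas = 0.37, pollutant = "p")
  expect_equal(composite_ef(flat, two, "p", 6, 50, 45)$value, 0.37)
})

test_that("composite EF is convex in the class factors", {
  set.seed(21)
  for (i in 1:20) {
    efs <- runif(2, 0.001, 2)
    tab <- toy_ef_table(ef_diesel = efs[1], ef_gas = efs[2], pollutant = "p")
    w <- runif(8); w <- w / sum(w)
    mix <- fleet_mix("rand", stats::setNames(w, vehicle_classes()))
    v <- composite_ef(tab, mix, "p", sample(12, 1), runif(1, 0, 100),
                      runif(1, 2.5, 75))$value
    expect_gte(v, min(efs) - 1e-12)
    expect_lte(v, max(efs) + 1e-12)
  }
})

test_that("diesel percentages of the packaged urban mixes reproduce exactly", {
  mixes <- urban_fleet_mixes()
  expect_equal(diesel_fraction(mixes$interstate), 9.18)
  expect_equal(diesel_fraction(mixes$arterial), 5.23)
  gas <- fleet_mix("gas", c(LDGV = 0.8, LDGT1 = 0.2))
  expect_equal(diesel_fraction(gas), 0)
})

test_that("hourly activity multiplies AADT by the temporal factors", {
  wed <- as.POSIXct("2010-09-15 10:00:00", tz = "UTC")  # a Wednesday
  expect_equal(hourly_activity(24000, uniform_tafs(), wed), 1000)
  hourly <- matrix(1 / 24, 2, 24, dimnames = list(c("weekday", "weekend"), NULL))
  hourly["weekday", 11] <- 0.08
  hourly <- hourly / rowSums(hourly)
  # hand product with explicitly denormalised pieces
  tafs <- list(hourly = rbind(weekday = rep(0.08, 24), weekend = rep(0.08, 24)),
               dow = rep(1.1, 7), month = rep(0.9, 12))
  class(tafs) <- "taf_set"
  expect_equal(hourly_activity(10000, tafs, wed), 10000 * 0.08 * 1.1 * 0.9)
  expect_equal(hourly_activity(0, uniform_tafs(), wed), 0)
  # weekend day type on Saturday
  sat <- as.POSIXct("2010-09-18 10:00:00", tz = "UTC")
  t2 <- taf_set(rbind(weekday = rep(1, 24), weekend = c(rep(2, 12), rep(0, 12))),
                rep(1, 7), rep(1, 12))
  expect_equal(hourly_activity(2400, t2, sat), 2400 * (2 / 24))
})

test_that("link emission rate combines EF, activity and unit conversion", {
  tab <- toy_ef_table(ef_diesel = 0.5, ef_gas = 0.5, pollutant = "p")
  mix <- urban_fleet_mixes()$interstate
  link <- straight_link(aadt = 3600 * 24)  # uniform TAF: 3600 vehicles/hour
  m <- met_row(0.3, 200, NA, 300, 0.1, 3, timestamp = as.POSIXct("2010-09-15 10:00:00", tz = "UTC"))
  out <- link_emission_rate(link, tab, mix, uniform_tafs(), m, "p")
  expect_equal(out$e_per_mile, 0.5 * 3600)
  expect_equal(out$q, 1800 / 1609.344 / 3600, tolerance = 1e-9)
  expect_equal(out$q, 3.1069e-4, tolerance = 1e-4)
  # unit construction: EF 1 g/veh/mi and 1609.344*3600 vehicles -> 1 g/m/s
  link1 <- straight_link(aadt = 1609.344 * 3600 * 24)
  tab1 <- toy_ef_table(1, 1, "p")
  expect_equal(link_emission_rate(link1, tab1, mix, uniform_tafs(), m, "p")$q, 1)
  # zero activity
  link0 <- straight_link(aadt = 0)
  out0 <- link_emission_rate(link0, tab, mix, uniform_tafs(), m, "p")
  expect_equal(c(out0$e_per_mile, out0$q), c(0, 0))
  # missing temperature flags the emission missing, not zero
  mm <- met_row(0.3, 200, NA, 300, 0.1, 3, temp_f = NA,
                timestamp = as.POSIXct("2010-09-15 10:00:00", tz = "UTC"))
  expect_true(is.na(link_emission_rate(link, tab, mix, uniform_tafs(), mm, "p")$e_per_mile))
})

test_that("emissions are linear in AADT and in every temporal factor", {
  tab <- toy_ef_table(0.3, 0.01, "p")
  mix <- urban_fleet_mixes()$arterial
  m <- met_row(0.3, 200, NA, 300, 0.1, 3, timestamp = as.POSIXct("2010-09-16 07:00:00", tz = "UTC"))
  base <- link_emission_rate(straight_link(aadt = 40000), tab, mix, uniform_tafs(), m, "p")
  twice <- link_emission_rate(straight_link(aadt = 80000), tab, mix, uniform_tafs(), m, "p")
  expect_equal(twice$e_per_mile, 2 * base$e_per_mile)
  scaled <- list(hourly = matrix(3 / 24, 2, 24, dimnames = list(c("weekday", "weekend"), NULL)),
                 dow = rep(1, 7), month = rep(1, 12))
  class(scaled) <- "taf_set"
  tripled <- link_emission_rate(straight_link(aadt = 40000), tab, mix, scaled, m, "p")
  expect_equal(tripled$e_per_mile, 3 * base$e_per_mile)
})

test_that("normalised temporal factors conserve annual activity within 0.1%", {
  tafs <- make_tafs()
  expect_equal(rowSums(tafs$hourly), c(weekday = 1, weekend = 1), tolerance = 1e-9)
  expect_equal(mean(tafs$dow), 1, tolerance = 1e-9)
  expect_equal(mean(tafs$month), 1, tolerance = 1e-9)
  ts <- hours_utc("2010-01-01 00:00:00", 365 * 24)
  total <- sum(hourly_activity(1000, tafs, ts))
  expect_equal(total, 365 * 1000, tolerance = 1e-3)
})

test_that("fleet ratio isolates the fleet-mix effect", {
  tab <- toy_ef_table(0.3, 0.01, "p")
  mixes <- urban_fleet_mixes()
  expect_equal(fleet_ratio(tab, mixes$interstate, mixes$interstate, "p", 8, 50, 45), 1)
  # hand arithmetic with the printed columns renormalised by their sums
  hd <- (9.18 * 0.3 + 90.92 * 0.01) / 100.10
  ld <- (5.23 * 0.3 + 94.78 * 0.01) / 100.01
  expect_equal(fleet_ratio(tab, mixes$interstate, mixes$arterial, "p", 8, 50, 45),
               hd / ld, tolerance = 1e-9)
  expect_equal(hd / ld, 1.454, tolerance = 1e-3)
  # a class-uniform pollutant is insensitive to any fleet mix
  flat <- toy_ef_table(2, 2, "p")
  expect_equal(fleet_ratio(flat, mixes$interstate, mixes$other, "p", 8, 50, 45), 1)
})

test_that("diesel-heavy pollutants have fleet ratio above 1 for diesel-heavier mixes", {
  set.seed(5)
  mixes <- urban_fleet_mixes()
  for (i in 1:10) {
    efd <- runif(1, 0.05, 1); efg <- runif(1, 0.001, efd * 0.5)
    tab <- toy_ef_table(efd, efg, "p")
    expect_gt(fleet_ratio(tab, mixes$interstate, mixes$arterial, "p", 8, 50, 45), 1)
  }
})

test_that("fleet mixes, EF tables and TAFs round-trip through CSV", {
  mixes <- urban_fleet_mixes()
  p <- withr::local_tempfile(fileext = ".csv")
  write_fleet_mixes(mixes, p)
  back <- read_fleet_mixes(p)
  expect_equal(names(back), names(mixes))
  expect_equal(back$interstate$fractions, mixes$interstate$fractions)

  tab <- toy_ef_table(0.2, 0.05, "p")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ef_table(tab, p2)
  expect_equal(read_ef_table(p2)$arr, tab$arr)

  tafs <- make_tafs()
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_tafs(tafs, p3)
  back3 <- read_tafs(p3)
  expect_equal(back3$hourly, tafs$hourly, tolerance = 1e-12)
  expect_equal(back3$dow, tafs$dow, tolerance = 1e-12)
  expect_equal(back3$month, tafs$month, tolerance = 1e-12)
})
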