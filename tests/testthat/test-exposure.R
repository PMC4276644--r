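test_that("hour validity requires complete records and 0.5 m/s wind", {
  df <- tibble::tibble(timestamp = hours_utc("2010-08-02 00:00:00", 3),
                       ustar = 0.3, L = c(200, 200, NA), zic = NA, zim = 300,
                       z0 = 0.1, u = c(0.4, 0.5, 3), wdir = 0, temp_f = 55)
  expect_equal(hour_valid(met_hours(df)), c(FALSE, TRUE, FALSE))
})

test_that("combination is the emissions-weighted sum over links", {
  ts <- hours_utc("2010-08-02 10:00:00", 1)
  chi <- toy_chi(array(50, c(1, 1, 1)), "L1", "r1", ts)
  emis <- tibble::tibble(link_id = "L1", timestamp = ts, pollutant = "p",
                         e_per_mile = NA_real_, q = 2e-4)
  out <- combine_concentrations(chi, emis, "p")
  expect_equal(out$c, 0.01)
  expect_true(out$valid)
  # zero emissions give zero everywhere
  emis0 <- emis; emis0$q <- 0
  expect_equal(combine_concentrations(chi, emis0, "p")$c, 0)
  # unknown links are rejected
  bad <- emis; bad$link_id <- "nope"
  expect_error(combine_concentrations(chi, bad, "p"), "absent")
})

test_that("combination is linear and superposes over links", {
  ts <- hours_utc("2010-08-02 10:00:00", 3)
  set.seed(13)
  arr <- array(runif(2 * 2 * 3, 10, 100), c(2, 2, 3))
  chi <- toy_chi(arr, c("L1", "L2"), c("r1", "r2"), ts)
  emis <- tibble::tibble(link_id = rep(c("L1", "L2"), each = 3),
                         timestamp = rep(ts, 2), pollutant = "p",
                         e_per_mile = NA_real_, q = runif(6, 1e-5, 1e-3))
  both <- combine_concentrations(chi, emis, "p")
  one <- combine_concentrations(toy_chi(arr[1, , , drop = FALSE], "L1", c("r1", "r2"), ts),
                                emis[emis$link_id == "L1", ], "p")
  two <- combine_concentrations(toy_chi(arr[2, , , drop = FALSE], "L2", c("r1", "r2"), ts),
                                emis[emis$link_id == "L2", ], "p")
  expect_equal(both$c, one$c + two$c, tolerance = 1e-12)
  doubled <- emis; doubled$q <- 2 * doubled$q
  expect_equal(combine_concentrations(chi, doubled, "p")$c, 2 * both$c, tolerance = 1e-12)
})

test_that("period averages enforce the 75% completeness rule", {
  # one receptor, one day; AM-peak (2 h) has 1 valid hour -> dropped,
  # mid-day (7 h) has 6 valid -> reported
  ts <- hours_utc("2010-08-02 00:00:00", 24)
  hrs <- as.POSIXlt(ts, tz = "UTC")$hour
  valid <- rep(TRUE, 24)
  valid[hrs == 7] <- FALSE          # AM-peak: 1/2 valid
  valid[hrs == 9] <- FALSE          # mid-day: 6/7 valid
  conc <- tibble::tibble(receptor_id = "r1", timestamp = ts, pollutant = "p",
                         c = ifelse(valid, as.numeric(hrs), NA), valid = valid)
  ps <- period_average(conc)
  cells <- ps$cells
  am <- cells[cells$period == "ampeak", ]
  expect_false(am$reported)
  expect_true(is.na(am$mean_c))
  md <- cells[cells$period == "midday", ]
  expect_true(md$reported)
  expect_equal(md$mean_c, mean(c(10, 11, 12, 13, 14, 15)))
  # daily cell: 22/24 valid >= 0.75
  daily <- cells[cells$period == "daily", ]
  expect_true(daily$reported)
  # fully valid period is a plain mean
  op2 <- cells[cells$period == "offpeak2", ]
  expect_equal(op2$mean_c, mean(19:23))
})

test_that("period summary statistics are ordered", {
  set.seed(31)
  ts <- hours_utc("2010-08-02 00:00:00", 24 * 12)
  conc <- tibble::tibble(receptor_id = rep(c("a", "b"), each = length(ts)),
                         timestamp = rep(ts, 2), pollutant = "p",
                         c = rexp(2 * length(ts)), valid = TRUE)
  st <- period_average(conc)$stats
  expect_true(all(st$min <= st$p5 + 1e-12))
  expect_true(all(st$p5 <= st$median + 1e-12))
  expect_true(all(st$median <= st$p95 + 1e-12))
  expect_true(all(st$p95 <= st$max + 1e-12))
  expect_true(all(st$min <= st$mean & st$mean <= st$max))
})

make_class_net <- function() {
  road_links(dplyr::bind_rows(
    tibble::as_tibble(straight_link("HD", -5000, 0, 5000, 0, nfc = 11L, aadt = 90000)),
    tibble::as_tibble(straight_link("LD", -5000, 1000, 5000, 1000, nfc = 12L, aadt = 80000)),
    tibble::as_tibble(straight_link("ART", -5000, 3000, 5000, 3000, nfc = 14L, aadt = 12000))))
}

test_that("cohort classification applies radii, thresholds and HD precedence", {
  links <- make_class_net()
  recs <- receptors(tibble::tibble(
    id = c("near_hd", "both", "near_ld", "far", "near_art"),
    x = 0,
    y = c(-100,   # 100 m from HD only
          800,    # 200 m from HD? no: 800 from HD, 200 from LD -> HTLD
          1120,   # 120 m from LD
          -2000,  # beyond 300 m of everything
          3100))) # 100 m from an arterial: not high-traffic, so LT
  out <- classify_receptors(recs, links)
  expect_equal(out$group_label[out$id == "near_hd"], "HTHD")
  expect_equal(out$group_label[out$id == "near_ld"], "HTLD")
  expect_equal(out$group_label[out$id == "far"], "LT")
  expect_equal(out$group_label[out$id == "near_art"], "LT")
  # precedence: within range of both HD and LD
  both <- receptors(tibble::tibble(id = "b", x = 0, y = 800))
  links2 <- links
  links2$geometry[[2]] <- rbind(c(-5000, 920), c(5000, 920))  # LD 120 m away
  out2 <- classify_receptors(receptors(tibble::tibble(id = "b", x = 0, y = 700)), links2)
  # 700 m from HD is out of range; 220 m from LD -> HTLD
  expect_equal(out2$group_label, "HTLD")
  out3 <- classify_receptors(receptors(tibble::tibble(id = "b", x = 0, y = 200)), links)
  # 200 m from HD and 800 from LD -> HTHD
  expect_equal(out3$group_label, "HTHD")
  out4 <- classify_receptors(receptors(tibble::tibble(id = "b", x = 0, y = 850)), links2)
  # 850 from HD (out), 70 from LD -> HTLD, and very-near flag set
  expect_true(out4$within_verynear)
  # within range of both: 250 m from HD, 120 m from LD -> HD takes precedence
  links3 <- links
  links3$geometry[[2]] <- rbind(c(-5000, 370), c(5000, 370))
  out5 <- classify_receptors(receptors(tibble::tibble(id = "b", x = 0, y = 250)), links3)
  expect_equal(out5$group_label, "HTHD")
  # labels exhaust the receptor set
  expect_true(all(out$group_label %in% c("HTHD", "HTLD", "LT")))
})

test_that("distance decay uses effective distance over downwind hours only", {
  links <- make_class_net()
  recs <- classify_receptors(
    receptors(tibble::tibble(id = "r1", x = 0, y = -100)), links)
  expect_equal(recs$nearest_ht_link, "HD")
  ts <- hours_utc("2010-08-02 00:00:00", 4)
  met <- met_hours(tibble::tibble(
    timestamp = ts, ustar = 0.3, L = 200, zic = NA, zim = 300, z0 = 0.1,
    u = 3, wdir = c(0, 60, 0, 60), temp_f = 55))
  conc <- tibble::tibble(receptor_id = "r1", timestamp = ts, pollutant = "p",
                         c = c(4, 2, 4, 2), valid = TRUE)
  prof <- distance_decay_profile(conc, recs, links, met)
  # wind alternates along-normal (100 m) and 60 degrees off (200 m)
  expect_equal(prof$mean_effective_distance, 150)
  expect_equal(prof$n_downwind, 4L)
  expect_equal(prof$mean_c, 3)
  # all hours upwind: distance absent, concentration still reported
  met_up <- met_hours(tibble::tibble(
    timestamp = ts, ustar = 0.3, L = 200, zic = NA, zim = 300, z0 = 0.1,
    u = 3, wdir = 180, temp_f = 55))
  prof_up <- distance_decay_profile(conc, recs, links, met_up)
  expect_true(is.na(prof_up$mean_effective_distance))
  expect_equal(prof_up$n_downwind, 0L)
  expect_equal(prof_up$mean_c, 3)
})
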