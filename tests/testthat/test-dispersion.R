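regimes <- stability_regimes()

test_that("stability classification follows the Monin-Obukhov bands", {
  expect_equal(classify_stability(-12.9), "convective")
  expect_equal(classify_stability(104.5), "stable")
  expect_equal(classify_stability(12.8), "very stable")
  expect_equal(classify_stability(-1223.7), "neutral")
  # band edges and the shallow positive range
  expect_equal(classify_stability(c(-500, 500, 100, 0.5, 501, -501)),
               c("convective", "stable", "very stable", "very stable",
                 "neutral", "neutral"))
  expect_error(classify_stability(0), "nonzero")
})

test_that("derived meteorology reproduces hand arithmetic for the regime rows", {
  cst <- dispersion_constants()
  conv <- derive_met(regime_met_hour("convective"), cst)
  expect_equal(conv$wstar, 0.229 * (80 / (0.4 * 12.9))^(1 / 3), tolerance = 1e-9)
  expect_equal(conv$wstar, 0.571, tolerance = 1e-3)
  neut <- derive_met(regime_met_hour("neutral"), cst)
  expect_equal(neut$sigma_v, 1.9 * 0.734)  # no convective contribution
  expect_equal(neut$u_e, sqrt(4.63^2 + 2 * (1.9 * 0.734)^2), tolerance = 1e-9)
  expect_equal(neut$u_e, 5.033, tolerance = 1e-3)
  stab <- derive_met(regime_met_hour("stable"), cst)
  expect_equal(stab$wstar, 0)
  vs <- derive_met(regime_met_hour("very stable"), cst)
  expect_equal(vs$sigma_v, cst$sigma_v_min)  # floor engages at low ustar
  # invariants
  for (d in list(conv, neut, stab, vs)) {
    expect_gte(d$u_e, d$u)
    expect_gte(d$sigma_v, cst$sigma_v_min)
  }
  bad <- regime_met_hour("stable"); bad$L <- 0; bad$complete <- TRUE
  expect_error(derive_met(bad), "L = 0")
})

test_that("plume spread curves have the stated limits and grow monotonically", {
  cst <- dispersion_constants()
  for (rg in regimes$regime) {
    d <- derive_met(regime_met_hour(rg), cst)
    s <- sigma_curves(c(0.01, 0.02), d, cst)
    t <- c(0.01, 0.02) / d$u_e
    expect_equal(s$sigma_y, d$sigma_v * t, tolerance = 1e-4)  # ballistic limit
    expect_equal(s$sigma_z, d$sigma_w * t, tolerance = 1e-4)
    x <- c(5, 10, 20, 50, 100, 200, 400, 800)
    sx <- sigma_curves(x, d, cst)
    expect_true(all(diff(sx$sigma_y) > 0))
    expect_true(all(diff(sx$sigma_z) > 0))
  }
  dc <- derive_met(regime_met_hour("convective"), cst)
  expect_equal(sigma_curves(100, dc, cst)$sigma_z, dc$sigma_w * 100 / dc$u_e)
  expect_error(sigma_curves(0, dc, cst), "> 0")
})

test_that("mirrored receptors see equal concentrations under along-road wind", {
  mat <- rbind(c(-3000, 0), c(3000, 0))
  for (rg in c("convective", "neutral")) {
    m <- regime_met_hour(rg, wdir = 270)  # wind from the west, along the road
    a <- unit_concentration(mat, c(200, 150), m)
    b <- unit_concentration(mat, c(200, -150), m)
    expect_gt(a, 0)
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("kernel matches the infinite-line closed form in its validity regime", {
  cst <- dispersion_constants(meander = FALSE, h_src = 0)
  m <- regime_met_hour("neutral", wdir = 0)
  mat <- rbind(c(-5000, 0), c(5000, 0))
  d <- derive_met(m, cst)
  for (x in c(50, 100, 200)) {
    sz <- sigma_curves(x, d, cst)$sigma_z
    closed <- sqrt(2 / pi) / (d$u_e * sz) * 1e6
    got <- unit_concentration(mat, c(0, -x, 0), m, cst)
    expect_equal(got, closed, tolerance = 0.01)
  }
})

test_that("adaptive integration agrees with a 10,000-element brute-force oracle", {
  set.seed(99)
  cst <- dispersion_constants()
  for (i in 1:20) {
    ang <- runif(1, 0, pi)
    len <- runif(1, 500, 5000)
    mat <- rbind(c(-cos(ang), -sin(ang)), c(cos(ang), sin(ang))) * len / 2
    rg <- sample(regimes$regime, 1)
    m <- regime_met_hour(rg, wdir = runif(1, 0, 360))
    r_ang <- runif(1, 0, 2 * pi)
    r_d <- runif(1, 20, 500)
    rec <- c(cos(r_ang), sin(r_ang)) * (len / 2 + r_d) * runif(1, 0.1, 1)
    if (perpendicular_distance(mat, rec) < 5) rec <- rec + c(0, 10)
    got <- unit_concentration(mat, rec, m, cst)
    want <- chi_oracle(mat, rec, m, cst)
    denom <- max(want, 1e-9)
    expect_lt(abs(got - want) / denom, 0.005)
  }
})

test_that("vertical flux through a downwind plane conserves the emitted mass", {
  # 1 g/m/s line source, perpendicular wind: the flux density per metre of
  # crosswind distance integrates to 1 g/m/s at any downwind plane.
  cst <- dispersion_constants(meander = FALSE)
  mat <- rbind(c(-10000, 0), c(10000, 0))
  for (rg in c("neutral", "stable")) {
    m <- regime_met_hour(rg, wdir = 0)
    d <- derive_met(m, cst)
    for (x in c(50, 150)) {
      sz <- sigma_curves(x, d, cst)$sigma_z
      expect_lt(sz, 0.8 * d$z_mix)
      zs <- seq(0, 8 * sz, length.out = 161)
      chiz <- vapply(zs, function(z) unit_concentration(mat, c(0, -x, z), m, cst),
                     numeric(1))
      flux <- sum((chiz[-1] + chiz[-length(chiz)]) / 2 * diff(zs)) * d$u_e / 1e6
      expect_equal(flux, 1, tolerance = 0.02)
    }
  }
})

test_that("meander produces nonzero upwind concentrations near the road", {
  mat <- rbind(c(-5000, 0), c(5000, 0))
  for (rg in c("convective", "very stable")) {
    m <- regime_met_hour(rg, wdir = 180)  # transport away from the receptor
    up_on <- unit_concentration(mat, c(0, -20), m)
    up_off <- unit_concentration(mat, c(0, -20), m, dispersion_constants(meander = FALSE))
    expect_gt(up_on, 0)
    expect_lt(up_off, 1e-6 * up_on)
  }
})

test_that("concentration decays monotonically with downwind distance", {
  for (rg in regimes$regime) {
    tp <- transect_profile(regime_met_hour(rg), distances = seq(5, 500, by = 15))
    expect_true(all(diff(tp$chi) < 0))
  }
})

test_that("stability ordering at 100 m: very stable > stable > neutral", {
  chi100 <- vapply(c("very stable", "stable", "neutral"), function(rg) {
    transect_profile(regime_met_hour(rg), distances = 100)$chi
  }, numeric(1))
  expect_gt(chi100[["very stable"]], chi100[["stable"]])
  expect_gt(chi100[["stable"]], chi100[["neutral"]])
})

test_that("normalized profiles start at one and preserve ratios", {
  expect_equal(normalized_profile(c(10, 5, 2)), c(1, 0.5, 0.2))
  expect_error(normalized_profile(c(0, 5)), "positive")
  dist <- seq(10, 210, by = 40)
  nv <- normalized_profile(transect_profile(regime_met_hour("very stable"),
                                            distances = dist)$chi)
  nn <- normalized_profile(transect_profile(regime_met_hour("neutral"),
                                            distances = dist)$chi)
  expect_equal(nv[1], 1)
  # shallower fall-off under strong stratification
  expect_true(all(nv[-1] >= nn[-1]))
})

test_that("chi matrices mask invalid hours and superpose linearly", {
  links <- road_links(dplyr::bind_rows(
    tibble::as_tibble(straight_link("L1", -2000, 0, 2000, 0)),
    tibble::as_tibble(straight_link("L2", -2000, 400, 2000, 400, nfc = 12L))))
  recs <- receptors(tibble::tibble(id = c("r1", "r2"), x = c(0, 500), y = c(-80, -150)))
  rg <- stability_regimes()
  met <- met_hours(tibble::tibble(
    timestamp = hours_utc("2010-09-15 06:00:00", 5),
    ustar = c(rg$ustar, 0.3), L = c(rg$L, 200), zic = c(rg$zic, NA),
    zim = c(rg$zim, 300), z0 = c(rg$z0, 0.1),
    u = c(rg$u, 0.4),  # last hour is calm
    wdir = 315, temp_f = 55))
  cm <- build_chi_matrix(links, recs, met)
  expect_equal(dim(cm$chi), c(2, 2, 5))
  expect_equal(cm$valid, c(rep(TRUE, 4), FALSE))
  expect_true(all(is.na(cm$chi[, , 5])))
  expect_true(all(cm$chi[, , 1:4] >= 0))
  # single-link runs superpose exactly: chi rows are computed independently
  cm1 <- build_chi_matrix(links[1, ], recs, met)
  expect_equal(cm$chi[1, , 1:4], cm1$chi[1, , 1:4])
  expect_error(build_chi_matrix(links[0, ], recs, met), "empty")
  # receptor sitting on a centerline is rejected
  on_road <- receptors(tibble::tibble(id = "bad", x = 0, y = 0))
  expect_error(build_chi_matrix(links, on_road, met), "centerline")
})

test_that("chi matrices round-trip through the long CSV format", {
  links <- straight_link("L1", -2000, 0, 2000, 0)
  recs <- receptors(tibble::tibble(id = c("r1", "r2"), x = c(0, 100), y = c(-80, -150)))
  met <- met_hours(tibble::tibble(
    timestamp = hours_utc("2010-09-15 06:00:00", 2),
    ustar = 0.3, L = c(200, NA), zic = NA, zim = 300, z0 = 0.1,
    u = 3, wdir = c(0, 10), temp_f = 55))
  cm <- build_chi_matrix(links, recs, met)
  p <- withr::local_tempfile(fileext = ".csv")
  write_chi(cm, p)
  back <- read_chi(p)
  expect_equal(back$chi, cm$chi, tolerance = 1e-12)
  expect_equal(back$valid, cm$valid)
  expect_equal(back$timestamps, cm$timestamps)
})
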