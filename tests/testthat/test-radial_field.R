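test_that("radial grid geometry and validation", {
  g <- radial_grid(bw = 20, r_max = 5000, h = 10000)
  expect_identical(g$J, 250L)
  expect_identical(g$edges[1], 0)
  expect_equal(diff(g$edges), rep(20, 250))
  expect_equal(sum(g$volumes_L), pi * 5000^2 * 10000 * 1e-24)
  expect_error(radial_grid(bw = 30, r_max = 100), "multiple")
  expect_error(radial_grid(bw = 50, r_max = 100), "3 bins")
})

test_that("bin_positions converts counts to molarities", {
  g <- radial_grid(bw = 20, r_max = 5000, h = 10000)
  pos <- data.frame(species = "OH", x_nm = 10, y_nm = 0, z_nm = 500)
  st <- bin_positions(pos, g, species = "OH")
  v0 <- pi * 20^2 * 10000 * 1e-24            # first annulus volume, litres
  expect_equal(unname(st$conc[1, "OH"]), 1 / (AVOGADRO * v0))
  expect_equal(unname(st$conc[1, "OH"]), 1.32e-7, tolerance = 1e-2)
  expect_true(all(st$conc[-1, ] == 0))
  expect_identical(attr(st, "discarded"), 0L)

  # per-track averaging halves concentrations when n_tracks doubles
  st2 <- bin_positions(pos, g, species = "OH", n_tracks = 2)
  expect_equal(st2$conc, st$conc / 2)

  # empty list -> all-zero fields
  st0 <- bin_positions(pos[0, ], g, species = c("OH", "H"))
  expect_true(all(st0$conc == 0))

  # out-of-cylinder positions are rejected and counted
  bad <- data.frame(species = c("OH", "OH", "OH"),
                    x_nm = c(5000, 10, 10), y_nm = c(0, 0, 0),
                    z_nm = c(100, -5, 20000))
  stb <- bin_positions(bad, g, species = "OH")
  expect_identical(attr(stb, "discarded"), 3L)
  expect_true(all(stb$conc == 0))
})

test_that("total_amount inverts binning and handles flat fields", {
  g <- radial_grid(bw = 20, r_max = 2000, h = 5000)
  set.seed(4)
  n <- 1000
  r <- sqrt(runif(n)) * 1999
  th <- runif(n, 0, 2 * pi)
  pos <- data.frame(species = "H2O2", x_nm = r * cos(th), y_nm = r * sin(th),
                    z_nm = runif(n, 0, 5000))
  st <- bin_positions(pos, g, species = "H2O2")
  expect_equal(unname(state_totals(st)["H2O2"]), n, tolerance = 1e-9)

  expect_identical(total_amount(rep(0, g$J), g), 0)
  cflat <- 2.5e-7
  expect_equal(total_amount(rep(cflat, g$J), g),
               cflat * AVOGADRO * pi * 2000^2 * 5000 * 1e-24)
})

test_that("G-values are per 100 eV and intensive in h", {
  g <- radial_grid(bw = 20, r_max = 2000, h = 10000)
  beam <- beam_spec(let = 10)
  # state holding exactly 1000 molecules per track
  c0 <- 1000 / (AVOGADRO * sum(g$volumes_L))
  st <- flat_state(g, list(OH = c0))
  gv <- gvalues(st, beam)      # E_dep = 10 keV/um * 10 um = 1e5 eV
  expect_equal(unname(gv["OH"]), 1.0)

  g2 <- radial_grid(bw = 20, r_max = 2000, h = 20000)
  st2 <- flat_state(g2, list(OH = c0))
  expect_equal(gvalues(st2, beam), gv, ignore_attr = TRUE)

  # G scales inversely with LET at fixed fields
  gv2 <- gvalues(st, beam_spec(let = 20))
  expect_equal(unname(gv2["OH"]), 0.5)

  expect_equal(unname(gvalues(flat_state(g, list(OH = 0)), beam)["OH"]), 0)
})

test_that("category sums partition the standard species", {
  expect_setequal(unlist(species_categories), STANDARD_SPECIES)
  expect_identical(anyDuplicated(unlist(species_categories)), 0L)
  g <- small_grid()
  cc <- 3e-8
  st <- flat_state(g, setNames(as.list(rep(cc, 10)), STANDARD_SPECIES))
  cs <- category_sums(st)
  expect_equal(unname(cs[1, ]), c(4, 3, 3) * cc)

  only_oh <- setNames(as.list(rep(0, 10)), STANDARD_SPECIES)
  only_oh$OH <- 1e-7
  cs2 <- category_sums(flat_state(g, only_oh))
  expect_equal(cs2[, "i"], rep(1e-7, g$J))
  expect_true(all(cs2[, c("ii", "iii")] == 0))
})

test_that("deviation is the relative total-amount difference", {
  g <- small_grid()
  a <- flat_state(g, list(A = 1.02e-6, B = 0, C = 1e-6))
  b <- flat_state(g, list(A = 1e-6, B = 0, C = 1e-6))
  d <- deviation(a, b)
  expect_equal(unname(d["A"]), 0.02)
  expect_equal(unname(d["C"]), 0)
  expect_true(is.na(d["B"]))
  expect_identical(attr(d, "skipped"), "B")
  z <- flat_state(g, list(A = 0, B = 0, C = 0))
  expect_equal(unname(deviation(z, b)["A"]), -1)
  expect_error(deviation(a, flat_state(g, list(X = 1e-6))), "species sets")
})

test_that("dose-LET-fluence geometry", {
  expect_equal(dose_from_fluence(beam_spec(let = 1, fluence = 6.25e8)), 1.0)
  s <- surface_from_fluence(beam_spec(let = 10, fluence = 1e7))
  expect_equal(s$S_cm2, 1e-7)
  expect_equal(s$r_max_nm, sqrt(1e-7 / pi) * 1e7)
  # linearity: doubling fluence doubles dose, halves surface
  b1 <- beam_spec(let = 5, fluence = 2e8)
  b2 <- beam_spec(let = 5, fluence = 4e8)
  expect_equal(dose_from_fluence(b2), 2 * dose_from_fluence(b1))
  expect_equal(surface_from_fluence(b2)$S_cm2,
               surface_from_fluence(b1)$S_cm2 / 2)
  # beam_spec completes the dose/fluence pair via the same relation
  b3 <- beam_spec(let = 1, dose = 1)
  expect_equal(b3$fluence, 6.25e8)
  expect_error(dose_from_fluence(beam_spec(let = 1)))
})
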