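p0 <- fix_params()

test_that("total NADPH integrates v_NADPH x biomass over the culture", {
  # constant integrand: v = 2 mmol/gDCW/h, X = 1 gDCW/l, T = 5 h -> 10 mmol/l
  tr <- fake_trajectory(seq(0, 5, length.out = 101), v_nadph = rep(2, 101),
                        X = rep(1, 101), horizon = 5, glc = 1)
  expect_identical(tr$T, 5)
  expect_equal(total_nadph(tr), 10, tolerance = 1e-12)

  # zero biomass -> 0
  tr0 <- fake_trajectory(seq(0, 5, length.out = 101), rep(2, 101),
                         X = rep(0, 101), horizon = 5, glc = 1)
  expect_identical(total_nadph(tr0), 0)

  # exponential biomass against the closed-form integral
  mu <- 0.5; X0 <- 0.05; v <- 3; Tend <- 8
  tt <- seq(0, Tend, length.out = 801)
  tre <- fake_trajectory(tt, rep(v, length(tt)), X = X0 * exp(mu * tt),
                         horizon = Tend, glc = 1)
  exact <- v * X0 * (exp(mu * Tend) - 1) / mu
  expect_equal(total_nadph(tre), exact, tolerance = 1e-3)
})

test_that("anabolic demand is linear in final biomass", {
  expect_equal(anabolic_demand(1, p0), 14.849)
  expect_identical(anabolic_demand(0, p0), 0)
  expect_equal(anabolic_demand(2, p0), 29.698)
  expect_error(anabolic_demand(-1, p0))
})

test_that("productivity = (total - demand)/T, unclamped, T > 0 required", {
  tt <- seq(0, 10, length.out = 201)
  # constant v * X integrates to total = 40; demand = 14.849 * X(T)
  tr <- fake_trajectory(tt, rep(4, 201), X = rep(1, 201), horizon = 10,
                        glc = 1)
  expect_equal(nadph_productivity(tr, p0), (40 - 14.849) / 10,
               tolerance = 1e-9)
  # demand > total -> negative, not clamped
  tr2 <- fake_trajectory(tt, rep(0.5, 201), X = rep(1, 201), horizon = 10,
                         glc = 1)
  expect_lt(nadph_productivity(tr2, p0), 0)
  # degenerate: already-depleted medium has T = 0
  tr3 <- fake_trajectory(tt, rep(1, 201), X = rep(1, 201), horizon = 10,
                         glc = 0)
  expect_identical(tr3$T, 0)
  expect_error(nadph_productivity(tr3, p0), "zero")
})

test_that("xylose scan satisfies the productivity identity and determinism", {
  grid <- seq(0, 100, by = 25)
  r1 <- xylose_scan("dptsG", 10, grid, params = p0)
  r2 <- xylose_scan("dptsG", 10, grid, params = p0)
  expect_identical(r1$table, r2$table)   # bitwise determinism
  tb <- r1$table
  expect_true(all(tb$ok))
  expect_equal(tb$nadph_productivity,
               (tb$total_nadph - tb$anabolic_demand) / tb$cultivation_time,
               tolerance = 1e-9)
  expect_equal(tb$nadph_availability, tb$total_nadph - tb$anabolic_demand,
               tolerance = 1e-9)
  # glucose/xylose split follows the content definition
  expect_equal(tb$content, grid)
  # argmax fields are contents from the grid
  expect_true(r1$argmax$nadph_productivity %in% grid)
})

test_that("argmax ties break toward the lower content", {
  grid <- seq(0, 100, by = 25)
  r <- xylose_scan("dptsG", 10, grid, params = p0)
  v <- r$table$nadph_productivity
  expect_identical(r$argmax$nadph_productivity,
                   r$table$content[which.max(v)])
})

test_that("doubling the dense-output resolution changes totals < 0.1%", {
  sc1 <- culture_scenario(glc = 2, xyl = 2, horizon = 30, n_out = 300)
  sc2 <- culture_scenario(glc = 2, xyl = 2, horizon = 30, n_out = 600)
  a <- simulate_batch(sc1, strain_preset("dptsG"), p0)
  b <- simulate_batch(sc2, strain_preset("dptsG"), p0)
  expect_lt(abs(total_nadph(a) - total_nadph(b)) / total_nadph(b), 1e-3)
})

test_that("the productivity optimum is insensitive to the inoculum", {
  grid <- seq(0, 40, by = 10)
  lo <- xylose_scan("dpgi", 10, grid, params = p0, biomass = 0.005)
  hi <- xylose_scan("dpgi", 10, grid, params = p0, biomass = 0.02)
  expect_lte(abs(lo$argmax$nadph_productivity -
                 hi$argmax$nadph_productivity), 20)
})

test_that("flux correlation matches, audits names, and validates input", {
  sim <- compute_fluxes(fix_state(), genotype(), p0)
  meas <- data.frame(reaction = names(sim), flux = as.numeric(sim))
  r <- flux_correlation(sim, meas)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_identical(r$n, length(sim))

  neg <- data.frame(reaction = names(sim), flux = -as.numeric(sim))
  expect_equal(flux_correlation(sim, neg)$r, -1, tolerance = 1e-12)

  # case-insensitive matching with an audit trail
  sub <- data.frame(reaction = c("pts", "PYK", "cs", "icdh"),
                    flux = c(1, 2, 3, 4))
  r2 <- flux_correlation(sim, sub)
  expect_setequal(r2$matched, c("PTS", "Pyk", "CS", "ICDH"))

  expect_error(flux_correlation(sim, sub[1:2, ]), "fewer than 3")
})

test_that("noisy synthetic flux measurements still correlate strongly", {
  # at noise sigma = 5% of the flux range the population correlation is
  # ~0.96; average over a few seeds to stay clear of single-draw spread
  rs <- vapply(1:5, function(seed) {
    f <- withr::local_tempfile(fileext = ".tsv")
    fx <- make_flux_fixture(f, seed = seed, params = p0)
    meas <- read_flux_table(f)
    r <- flux_correlation(fx$simulated, meas)
    # the utility agrees with a direct correlation of the same table
    expect_equal(r$r, stats::cor(as.numeric(fx$simulated), meas$flux),
                 tolerance = 1e-12)
    expect_lt(r$p_value, 0.01)
    r$r
  }, numeric(1))
  expect_gt(mean(rs), 0.95)

  # same seed reproduces the fixture exactly
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  make_flux_fixture(f1, seed = 42, params = p0)
  make_flux_fixture(f2, seed = 42, params = p0)
  expect_identical(readLines(f1), readLines(f2))
})
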