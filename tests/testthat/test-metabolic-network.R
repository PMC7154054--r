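p0 <- fix_params()

test_that("TF activities are bounded, monotone, and respect overrides", {
  st <- fix_state()
  tfs <- tf_activities(st, genotype(), p0)
  expect_true(all(tfs >= 0 & tfs <= 1))

  # cAMP-Crp non-decreasing in PEP/PYR ratio
  lo <- fix_state(PEP = 0.1, PYR = 2)
  hi <- fix_state(PEP = 2, PYR = 0.1)
  expect_lt(tf_activities(lo, genotype(), p0)[["Crp"]],
            tf_activities(hi, genotype(), p0)[["Crp"]])

  # Cra non-increasing in FBP, saturating repression limit
  expect_gt(tf_activities(fix_state(FBP = 0.05), genotype(), p0)[["Cra"]],
            tf_activities(fix_state(FBP = 10), genotype(), p0)[["Cra"]])
  expect_lt(tf_activities(fix_state(FBP = 1e9), genotype(), p0)[["Cra"]],
            1e-10)

  # XylR non-decreasing in intracellular xylose
  expect_lt(tf_activities(fix_state(XYLin = 0.01), genotype(), p0)[["XylR"]],
            tf_activities(fix_state(XYLin = 5), genotype(), p0)[["XylR"]])

  # ArcA override pins the activity regardless of state
  g <- overexpress_tf(genotype(), "ArcA", 0.95)
  expect_identical(tf_activities(fix_state(NADH = 0.01), g, p0)[["ArcA"]],
                   0.95)
  expect_identical(tf_activities(fix_state(NADH = 1.9), g, p0)[["ArcA"]],
                   0.95)
})

test_that("TF activity computation reports missing constants", {
  p <- p0
  p$K_Cra_FBP <- NULL
  expect_error(tf_activities(fix_state(), genotype(), p), "K_Cra_FBP")
})

test_that("regulated_vmax: identity, repression limit, hand evaluation", {
  tfs <- c(Crp = 0.7, Cra = 0.2, ArcA = 0.3, XylR = 0.4)
  # unregulated reaction returns vmax' exactly
  expect_identical(regulated_vmax("Pfk", tfs, params = p0), p0$vmax_Pfk)
  expect_error(regulated_vmax("NotAReaction", tfs, params = p0), "unknown")

  # full-repression limit with c0 = 0 and reference 0: f(1) = 0
  reg <- data.frame(tf = "ArcA", target = "CS", sign = "-", c0 = 0)
  p <- p0; p$ref_ArcA <- 0
  tfs1 <- c(Crp = 0, Cra = 0, ArcA = 1, XylR = 0)
  expect_equal(regulated_vmax("CS", tfs1, reg, p), 0)

  # xylose gene activated by cAMP-Crp and XylR: hand evaluation of f
  reg <- regulation_map()
  rows <- reg[reg$target == "XT", ]
  f_hand <- prod(vapply(seq_len(nrow(rows)), function(i) {
    c0 <- rows$c0[i]
    c0 + (1 - c0) * tfs[[rows$tf[i]]]
  }, numeric(1)))
  expect_equal(regulated_vmax("XT", tfs, reg, p0), p0$vmax_XT * f_hand,
               tolerance = 1e-12)

  # missing TF in activities vector is an error naming the TF
  expect_error(regulation_factor("XT", c(Cra = 0.5), reg, p0), "Crp")
})

test_that("regulation factors are monotone in each TF", {
  reg <- regulation_map()
  set.seed(11)
  for (i in 1:50) {
    tfs <- c(Crp = runif(1), Cra = runif(1), ArcA = runif(1),
             XylR = runif(1))
    for (target in unique(reg$target)) {
      rows <- reg[reg$target == target, ]
      f0 <- regulation_factor(target, tfs, reg, p0)
      for (j in seq_len(nrow(rows))) {
        up <- tfs
        up[rows$tf[j]] <- min(1, up[rows$tf[j]] + 0.2)
        f1 <- regulation_factor(target, up, reg, p0)
        if (rows$sign[j] == "+") expect_gte(f1, f0 - 1e-12)
        else expect_lte(f1, f0 + 1e-12)
      }
    }
  }
})

test_that("xylose rate laws match their closed-form limits", {
  tfs <- c(Crp = 0.8, Cra = 0.1, ArcA = 0.1, XylR = 0.9)
  fxt <- regulation_factor("XT", tfs, params = p0)
  fxi <- regulation_factor("Xyi", tfs, params = p0)
  fxk <- regulation_factor("Xyk", tfs, params = p0)
  sat_atp <- 1e12   # saturate the ATP dependence of the ABC transporter

  # zero substrate
  expect_identical(rate_xt(fix_state(XYL = 0), tfs, p0), 0)
  expect_identical(rate_xyi(fix_state(XYLin = 0), tfs, p0), 0)
  expect_identical(rate_xyk(fix_state(XYLU = 5, ATP = 0), tfs, p0), 0)

  # saturation: [EIIA] = 0 (phosphorelay fully phosphorylated), XYL -> Inf
  st <- fix_state(XYL = 1e12 * p0$MW_XYL / 1000, PEP = 1e12, PYR = 1e-9,
                  ATP = sat_atp)
  eiia <- eiia_state(st, p0)$EIIA
  expect_lt(eiia, 1e-8)
  expect_equal(rate_xt(st, tfs, p0), p0$vmax_XT * fxt, tolerance = 1e-6)

  # inducer-exclusion factor 1/3: [XYL] = K_XYL, [EIIA] = K_I
  p <- p0
  p$EIIA_total <- 2 * p$K_I   # with phi = 1/2, unphosphorylated EIIA = K_I
  r_half <- p$K_EIIA          # PEP/PYR ratio giving phi = 1/2
  st <- fix_state(XYL = p$K_XYL * p$MW_XYL / 1000, ATP = sat_atp,
                  PEP = r_half - 0.01, PYR = 1 - 0.01)
  expect_equal(eiia_state(st, p)$EIIA, p$K_I, tolerance = 1e-9)
  fxt_p <- regulation_factor("XT", tfs, params = p)
  expect_equal(rate_xt(st, tfs, p), p$vmax_XT * fxt_p / 3,
               tolerance = 1e-8)

  # isomerase half-saturation and saturation
  expect_equal(rate_xyi(fix_state(XYLin = p0$K_XYLin), tfs, p0),
               p0$vmax_Xyi * fxi / 2, tolerance = 1e-12)
  expect_equal(rate_xyi(fix_state(XYLin = 1e12), tfs, p0),
               p0$vmax_Xyi * fxi, tolerance = 1e-10)

  # xylulokinase quarter-rate at both half-saturations, full saturation
  expect_equal(rate_xyk(fix_state(XYLU = p0$K_XYLU, ATP = p0$K_Xyk_ATP),
                        tfs, p0),
               p0$vmax_Xyk * fxk / 4, tolerance = 1e-12)
  expect_equal(rate_xyk(fix_state(XYLU = 1e10, ATP = 1e10), tfs, p0),
               p0$vmax_Xyk * fxk, tolerance = 1e-9)
})

test_that("compute_fluxes matches an independent rate-law oracle", {
  st <- fix_state()
  v <- compute_fluxes(st, genotype(), p0)
  ov <- oracle_fluxes(st, p0)
  expect_equal(v[names(ov)], ov, tolerance = 1e-12)

  # with the mevalonate pathway enabled and intermediates populated
  st2 <- fix_state(AcAcCoA = 0.3, HMGCoA = 0.4)
  g <- strain_preset("MVA_dpgi_arcA")
  v2 <- compute_fluxes(st2, g, p0)
  tfs2 <- tf_activities(st2, g, p0)
  ov2 <- oracle_fluxes(st2, p0, tfs = tfs2, mva = TRUE)
  ov2[["Pgi"]] <- 0
  expect_equal(v2[names(ov2)], ov2, tolerance = 1e-12)

  # anaerobic: no oxidative phosphorylation
  v3 <- compute_fluxes(st, genotype(), p0, aerobic = FALSE)
  expect_identical(v3[["OP"]], 0)
})

test_that("knockouts zero fluxes exactly; empty cell carries no flux", {
  st <- fix_state()
  expect_identical(compute_fluxes(st, strain_preset("dpgi"), p0)[["Pgi"]], 0)
  expect_identical(compute_fluxes(st, strain_preset("dptsG"), p0)[["PTS"]], 0)
  expect_identical(compute_fluxes(st, strain_preset("dack"), p0)[["PTACK"]],
                   0)

  empty <- initial_state(glc = 0, xyl = 0, ace = 0, biomass = 0)
  empty[xyloflux:::.xf_intracellular] <- 0
  v <- compute_fluxes(empty, genotype(), p0)
  consuming <- setdiff(names(v), c("Pgi", "Rpe", "Rpi", "TktA", "Tal",
                                   "TktB"))
  expect_true(all(abs(v[consuming]) < 1e-12))
})

test_that("ATP rate is the signed sum over producing and consuming steps", {
  v <- compute_fluxes(fix_state(), genotype(), p0)
  v[] <- 0
  expect_identical(atp_rate(v), 0)
  v[c("OP", "L_Emp", "Pyk", "PTACK", "aKGDH", "Glk", "Pfk", "Pps", "Pck",
      "Acs", "XT", "Xyk")] <- c(10, 5, 3, 2, 1, 1, 2, 0, 0, 0, 1, 1)
  expect_identical(atp_rate(v), 16)
})

test_that("growth rate follows the acetate-inhibited ATP coupling", {
  v_atp <- 50
  expect_equal(growth_rate(v_atp, 0, p0), p0$k_ATP * v_atp)
  expect_equal(growth_rate(v_atp, p0$k_ACE, p0), p0$k_ATP * v_atp / 2)
  expect_lt(growth_rate(v_atp, 1e9, p0), 1e-6)
  expect_identical(growth_rate(-10, 0, p0), 0)   # clamped from below
  expect_error(growth_rate(v_atp, -1, p0))
})

test_that("NADPH rate sums the four production sites", {
  v <- compute_fluxes(fix_state(), genotype(), p0)
  v[] <- 0
  expect_identical(nadph_rate(v, p0), 0)
  v[c("G6PDH", "PGDH", "ICDH", "Mez")] <- 1:4
  expect_identical(nadph_rate(v, p0), 10)
  # alternate reading of the first production site
  p <- p0; p$nadph_first_term <- 0
  v[["L_Emp"]] <- 7
  expect_identical(nadph_rate(v, p), 7 + 2 + 3 + 4)
})
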