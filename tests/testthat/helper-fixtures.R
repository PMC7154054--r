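# Shared fixtures. Simulations are cached per test run; everything is built
# in code (no stored data files).

.fix <- new.env(parent = emptyenv())

fix_params <- function() default_params()

# deterministic, biologically plausible reference state for rate-law checks
fix_state <- function(...) {
  s <- initial_state(glc = 3, xyl = 2, ace = 0.2, biomass = 0.5)
  s[["XYLin"]] <- 0.8
  s[["XYLU"]] <- 0.6
  s[["GLX"]] <- 0.15
  over <- list(...)
  for (nm in names(over)) s[[nm]] <- over[[nm]]
  s
}

fix_batch <- function(key, preset, glc, xyl, horizon = 40, ...) {
  if (is.null(.fix[[key]])) {
    sc <- culture_scenario(glc = glc, xyl = xyl, horizon = horizon, ...)
    .fix[[key]] <- simulate_batch(sc, strain_preset(preset), fix_params())
  }
  .fix[[key]]
}

fix_wt_55    <- function() fix_batch("wt55", "WT", 5, 5)
fix_dpgi_55  <- function() fix_batch("dpgi55", "dpgi", 5, 5)
fix_dptsg_55 <- function() fix_batch("dptsg55", "dptsG", 5, 5)

# xylose consumed (g/l) at the time glucose first falls below `thr`
xyl_at_glc_depletion <- function(tr, thr = 0.05) {
  i <- which(tr$states[, "GLC"] <= thr)[1]
  if (is.na(i)) return(NA_real_)
  tr$scenario$xyl - tr$states[i, "XYL"]
}

# Independent one-by-one re-evaluation of every rate law, written as plain
# formulas against the model description (oracle for compute_fluxes).
oracle_fluxes <- function(st, p = fix_params(), tfs = NULL, aerobic = TRUE,
                          mva = FALSE) {
  if (is.null(tfs)) tfs <- tf_activities(st, genotype(), p, aerobic)
  mm <- function(S, K) S / (K + S)
  ADP <- p$A_total - st[["ATP"]]; NAD <- p$N_total - st[["NADH"]]
  NADP <- p$NP_total - st[["NADPH"]]
  glc <- st[["GLC"]] / p$MW_GLC * 1000
  xyl <- st[["XYL"]] / p$MW_XYL * 1000
  ace <- st[["ACE"]] / p$MW_ACE * 1000
  r <- (st[["PEP"]] + 0.01) / (st[["PYR"]] + 0.01)
  eiia <- p$EIIA_total * (1 - r / (p$K_EIIA + r))
  f <- function(target) regulation_factor(target, tfs, regulation_map(), p)
  rev1 <- function(A, B, vmax, Ka, Kb, Keq)
    vmax * (A / Ka - B / (Ka * Keq)) / (1 + A / Ka + B / Kb)
  rev2 <- function(A, B, P, Q, vmax, K, Keq)
    vmax * (A * B - P * Q / Keq) / ((K + A + P) * (K + B + Q))
  w <- function(nm) st[[nm]]
  out <- c(
    PTS = p$vmax_PTS * mm(glc, p$K_PTS_GLC) * mm(w("PEP"), p$K_PTS_PEP) /
      (1 + (w("G6P") / p$K_PTS_G6P)^p$n_PTS_G6P),
    NPTS = p$vmax_NPTS * f("NPTS") * glc /
      (p$K_NPTS_GLC + (1 + eiia / p$K_I_NPTS) * glc) *
      mm(w("ATP"), 0.3) / (1 + (w("G6P") / p$K_NPTS_G6P)^2),
    Pgi = rev1(w("G6P"), w("F6P"), p$vmax_Pgi, p$K_Pgi_G6P, p$K_Pgi_F6P,
               p$Keq_Pgi),
    Pfk = p$vmax_Pfk * mm(w("F6P"), p$K_Pfk_F6P) * mm(w("ATP"), p$K_Pfk_ATP),
    Fbp = p$vmax_Fbp * mm(w("FBP"), p$K_Fbp_FBP),
    Fba = p$vmax_Fba * mm(w("FBP"), p$K_Fba_FBP),
    L_Emp = p$vmax_Emp * mm(w("GAP"), p$K_Emp_GAP) * mm(NAD, p$K_Emp_NAD) *
      mm(ADP, p$K_Emp_ADP) / (1 + (w("NADH") / p$Ki_Emp_NADH)^p$n_Emp_NADH),
    Pyk = p$vmax_Pyk * f("Pyk") * mm(w("PEP"), p$K_Pyk_PEP) *
      mm(ADP, p$K_Pyk_ADP) *
      (p$a0_Pyk + (1 - p$a0_Pyk) * mm(w("FBP"), p$Ka_Pyk_FBP)),
    Pps = p$vmax_Pps * mm(w("PYR"), p$K_Pps_PYR) * mm(w("ATP"), p$K_Pps_ATP),
    PDH = p$vmax_PDH * mm(w("PYR"), p$K_PDH_PYR) * mm(NAD, p$K_PDH_NAD) /
      (1 + (w("NADH") / p$Ki_PDH_NADH)^p$n_PDH_NADH),
    Pfl = p$vmax_Pfl * f("Pfl") * mm(w("PYR"), p$K_Pfl_PYR),
    G6PDH = p$vmax_G6PDH * f("G6PDH") * mm(w("G6P"), p$K_G6PDH_G6P) *
      mm(NADP, p$K_G6PDH_NADP) /
      (1 + (w("NADPH") / p$Ki_G6PDH_NADPH)^p$n_G6PDH_NADPH),
    PGDH = p$vmax_PGDH * f("PGDH") * mm(w("PG6"), p$K_PGDH_PG6) *
      mm(NADP, p$K_PGDH_NADP),
    Rpe = rev1(w("Ru5P"), w("X5P"), p$vmax_Rpe, p$K_Rpe, p$K_Rpe, p$Keq_Rpe),
    Rpi = rev1(w("Ru5P"), w("R5P"), p$vmax_Rpi, p$K_Rpi, p$K_Rpi, p$Keq_Rpi),
    TktA = rev2(w("X5P"), w("R5P"), w("S7P"), w("GAP"), p$vmax_TktA,
                p$K_TktA, p$Keq_TktA),
    Tal = rev2(w("S7P"), w("GAP"), w("E4P"), w("F6P"), p$vmax_Tal,
               p$K_Tal, p$Keq_Tal),
    TktB = rev2(w("X5P"), w("E4P"), w("F6P"), w("GAP"), p$vmax_TktB,
                p$K_TktB, p$Keq_TktB),
    CS = p$vmax_CS * f("CS") * mm(w("AcCoA"), p$K_CS_AcCoA) *
      mm(w("OAA"), p$K_CS_OAA),
    ICDH = p$vmax_ICDH * f("ICDH") * mm(w("ICIT"), p$K_ICDH_ICIT) *
      mm(NADP, p$K_ICDH_NADP),
    aKGDH = p$vmax_aKGDH * f("aKGDH") * mm(w("AKG"), p$K_aKGDH_AKG) *
      mm(NAD, p$K_aKGDH_NAD) * mm(ADP, 0.3),
    SDH = p$vmax_SDH * f("SDH") * mm(w("SUC"), p$K_SDH_SUC) *
      mm(NAD, p$K_aKGDH_NAD),
    Fum = p$vmax_Fum * mm(w("FUM"), p$K_Fum_FUM),
    MDH = p$vmax_MDH * f("MDH") * mm(w("MAL"), p$K_MDH_MAL) *
      mm(NAD, p$K_MDH_NAD),
    Icl = p$vmax_Icl * mm(w("ICIT"), p$K_Icl_ICIT),
    MS = p$vmax_MS * mm(w("GLX"), p$K_MS_GLX) * mm(w("AcCoA"), p$K_MS_AcCoA),
    Ppc = p$vmax_Ppc * mm(w("PEP"), p$K_Ppc_PEP) /
      (1 + w("OAA") / p$Ki_Ppc_OAA),
    Pck = p$vmax_Pck * mm(w("OAA"), p$K_Pck_OAA) * mm(w("ATP"), p$K_Pck_ATP),
    Mez = p$vmax_Mez * mm(w("MAL"), p$K_Mez_MAL) * mm(NADP, p$K_Mez_NADP),
    PTACK = p$vmax_PTACK * mm(w("AcCoA"), p$K_PTACK_AcCoA) *
      mm(ADP, p$K_PTACK_ADP),
    Acs = p$vmax_Acs * f("Acs") * mm(ace, p$K_Acs_ACE) * mm(w("ATP"), 0.3),
    LDH = p$vmax_LDH * mm(w("PYR"), p$K_LDH_PYR) *
      w("NADH")^2 / (p$K_LDH_NADH^2 + w("NADH")^2),
    ADH = p$vmax_ADH * mm(w("AcCoA"), p$K_ADH_AcCoA) *
      w("NADH")^2 / (p$K_ADH_NADH^2 + w("NADH")^2),
    Udh = p$vmax_Udh * mm(w("NADPH"), p$K_Udh_NADPH) * mm(NAD, p$K_Udh_NAD),
    NOX = p$vmax_NOX * w("NADH")^p$n_NOX /
      (p$K_NOX_NADH^p$n_NOX + w("NADH")^p$n_NOX),
    XT = p$vmax_XT * f("XT") * mm(w("ATP"), p$K_XT_ATP) * xyl /
      (p$K_XYL + (1 + eiia / p$K_I) * xyl),
    Xyi = p$vmax_Xyi * f("Xyi") * mm(w("XYLin"), p$K_XYLin),
    Xyk = p$vmax_Xyk * f("Xyk") * w("XYLU") * w("ATP") /
      (p$K_XYLU * p$K_Xyk_ATP + p$K_Xyk_ATP * w("XYLU") +
         p$K_XYLU * w("ATP") + w("XYLU") * w("ATP")),
    OP = if (aerobic) {
      p$PO_ratio * p$vmax_resp * f("OP") * mm(w("NADH"), p$K_resp_NADH) *
        mm(ADP, p$K_resp_ADP)
    } else 0,
    ATPase = p$vmax_ATPase * mm(w("ATP"), p$K_ATPase_ATP),
    AtoB = if (mva) {
      p$vmax_AtoB * w("AcCoA")^p$n_AtoB /
        (p$K_AtoB_AcCoA^p$n_AtoB + w("AcCoA")^p$n_AtoB) /
        (1 + w("AcAcCoA") / p$Ki_AtoB_AcAcCoA)
    } else 0,
    HMGS = if (mva) {
      p$vmax_HMGS * mm(w("AcAcCoA"), p$K_HMGS_AcAcCoA) *
        mm(w("AcCoA"), p$K_HMGS_AcCoA) /
        (1 + w("HMGCoA") / p$Ki_HMGS_HMGCoA)
    } else 0,
    HMGR = if (mva) {
      p$vmax_HMGR * mm(w("HMGCoA"), p$K_HMGR_HMGCoA) *
        w("NADPH")^2 / (p$K_HMGR_NADPH^2 + w("NADPH")^2)
    } else 0
  )
  out[["Glk"]] <- out[["NPTS"]]
  out
}

# minimal hand-built trajectory object for the productivity arithmetic
fake_trajectory <- function(times, v_nadph, X, horizon = max(times),
                            glc = 0, xyl = 0) {
  states <- matrix(0, length(times), length(xyloflux:::.xf_species),
                   dimnames = list(NULL, xyloflux:::.xf_species))
  states[, "X"] <- X
  states[, "GLC"] <- glc
  states[, "XYL"] <- xyl
  tr <- structure(list(times = times, states = states,
                       v_NADPH = v_nadph,
                       scenario = list(horizon = horizon,
                                       depletion_threshold = 0.01),
                       params = fix_params()),
                  class = "xf_trajectory")
  tr$T <- cultivation_time(tr)
  tr
}
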