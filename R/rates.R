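# Rate laws for every reaction of the network. Fluxes are specific rates in
# mmol/gDCW/h; intracellular concentrations in mM; extracellular substrate
# concentrations are converted from g/l to mM before entering rate laws.
# Irreversible reactions use (possibly regulated) Michaelis-Menten forms with
# the documented allosteric effectors; reversible reactions (Pgi, the
# non-oxidative PP interconversions) use net reversible forms and may carry
# negative flux.

# reversible uni-uni: A <-> B
.rl_rev1 <- function(A, B, vmax, Ka, Kb, Keq) {
  vmax * (A / Ka - B / (Ka * Keq)) / (1 + A / Ka + B / Kb)
}

# reversible bi-bi: A + B <-> P + Q (shared half-saturation K)
.rl_rev2 <- function(A, B, P, Q, vmax, K, Keq) {
  vmax * (A * B - P * Q / Keq) / ((K + A + P) * (K + B + Q))
}

.mm <- function(S, K) S / (K + S)

# Compile the regulation map into a fast per-target evaluation structure.
.compile_regulation <- function(reg, p) {
  refs <- c(Crp = p$ref_Crp, Cra = p$ref_Cra, ArcA = p$ref_ArcA,
            XylR = p$ref_XylR)
  split_edges <- split(reg, reg$target)
  lapply(split_edges, function(df) {
    list(tf = df$tf, plus = df$sign == "+", c0 = df$c0,
         c1 = ifelse(df$sign == "+", 1 - df$c0,
                     (1 - df$c0) / (1 - refs[df$tf])))
  })
}

# Evaluate compiled regulation factor for one target (1 if unregulated).
.reg_eval <- function(compiled, target, tfs) {
  e <- compiled[[target]]
  if (is.null(e)) return(1)
  f <- 1
  for (i in seq_along(e$tf)) {
    a <- tfs[[e$tf[i]]]
    f <- f * if (e$plus[i]) e$c0[i] + e$c1[i] * a
             else max(e$c0[i] + e$c1[i] * (1 - a), 0)
  }
  f
}

# Knockout multiplier vector over reactions (1 = active, 0 = knocked out).
.ko_multipliers <- function(genotype) {
  map <- gene_reaction_map()
  ko <- map[genotype$knockouts]
  ko
}

#' Xylose transporter rate (inducer exclusion)
#'
#' \deqn{v_{XT} = v^{max'}_{XT} f(TF_{cAMP\mbox{-}Crp}, TF_{XylR})
#'   \frac{[XYL]}{K_{XYL} + (1 + [EIIA]/K_I)[XYL]}}
#' Unphosphorylated EIIA of the PTS raises the apparent saturation level,
#' excluding xylose uptake while glucose is being transported.
#'
#' @param state named state vector ([XYL] in g/l; converted internally).
#' @param tfs TF activities from [tf_activities()].
#' @param params an \code{xf_params} object.
#' @return Flux in mmol/gDCW/h, in \code{[0, vmax' f]}.
#' @export
rate_xt <- function(state, tfs, params = default_params()) {
  p <- params
  xyl <- max(state[["XYL"]], 0) / p$MW_XYL * 1000   # g/l -> mM
  eiia <- eiia_state(state, p)$EIIA
  f <- .reg_eval(.compile_regulation(regulation_map(), p), "XT", tfs)
  atp <- max(state[["ATP"]], 0)
  p$vmax_XT * f * atp / (p$K_XT_ATP + atp) * xyl /
    (p$K_XYL + (1 + eiia / p$K_I) * xyl)
}

#' Xylose isomerase rate
#'
#' Michaelis-Menten in intracellular xylose, transcriptionally scaled by
#' cAMP-Crp and XylR.
#'
#' @inheritParams rate_xt
#' @return Flux in mmol/gDCW/h.
#' @export
rate_xyi <- function(state, tfs, params = default_params()) {
  p <- params
  f <- .reg_eval(.compile_regulation(regulation_map(), p), "Xyi", tfs)
  p$vmax_Xyi * f * .mm(max(state[["XYLin"]], 0), p$K_XYLin)
}

#' Xylulokinase rate
#'
#' Two-substrate (xylulose, ATP) rate law scaled by cAMP-Crp and XylR:
#' \deqn{v = v^{max'} f \frac{[XYLU][ATP]}{K_{XYLU}K_{ATP} +
#'   K_{ATP}[XYLU] + K_{XYLU}[ATP] + [XYLU][ATP]}}
#'
#' @inheritParams rate_xt
#' @return Flux in mmol/gDCW/h.
#' @export
rate_xyk <- function(state, tfs, params = default_params()) {
  p <- params
  f <- .reg_eval(.compile_regulation(regulation_map(), p), "Xyk", tfs)
  xu <- max(state[["XYLU"]], 0); atp <- max(state[["ATP"]], 0)
  p$vmax_Xyk * f * xu * atp /
    (p$K_XYLU * p$K_Xyk_ATP + p$K_Xyk_ATP * xu + p$K_XYLU * atp + xu * atp)
}

# Core flux evaluation shared by compute_fluxes() and the ODE right-hand
# side. `ko` is a character vector of reactions to zero; `compiled` the
# compiled regulation map.
.flux_core <- function(state, p, ko, tfs, compiled, aerobic, mva) {
  s <- function(nm) max(state[[nm]], 0)
  cf <- .cofactor_partners(state, p)
  ADP <- cf$ADP; NAD <- cf$NAD; NADP <- cf$NADP

  glc <- s("GLC") / p$MW_GLC * 1000
  ace <- s("ACE") / p$MW_ACE * 1000
  eiia <- eiia_state(state, p)$EIIA

  fr <- function(target) .reg_eval(compiled, target, tfs)

  G6P <- s("G6P"); F6P <- s("F6P"); FBP <- s("FBP"); GAP <- s("GAP")
  PEP <- s("PEP"); PYR <- s("PYR"); AcCoA <- s("AcCoA"); PG6 <- s("PG6")
  Ru5P <- s("Ru5P"); X5P <- s("X5P"); R5P <- s("R5P"); S7P <- s("S7P")
  E4P <- s("E4P"); ICIT <- s("ICIT"); AKG <- s("AKG"); SUC <- s("SUC")
  FUM <- s("FUM"); MAL <- s("MAL"); OAA <- s("OAA"); GLX <- s("GLX")
  ATP <- s("ATP"); NADH <- s("NADH"); NADPH <- s("NADPH")

  v <- c(
    PTS = p$vmax_PTS * .mm(glc, p$K_PTS_GLC) * .mm(PEP, p$K_PTS_PEP) /
      (1 + (G6P / p$K_PTS_G6P)^p$n_PTS_G6P),
    NPTS = p$vmax_NPTS * fr("NPTS") * glc /
      (p$K_NPTS_GLC + (1 + eiia / p$K_I_NPTS) * glc) * .mm(ATP, 0.3) /
      (1 + (G6P / p$K_NPTS_G6P)^2),
    Pgi = .rl_rev1(G6P, F6P, p$vmax_Pgi, p$K_Pgi_G6P, p$K_Pgi_F6P, p$Keq_Pgi),
    Pfk = p$vmax_Pfk * .mm(F6P, p$K_Pfk_F6P) * .mm(ATP, p$K_Pfk_ATP),
    Fbp = p$vmax_Fbp * .mm(FBP, p$K_Fbp_FBP),
    Fba = p$vmax_Fba * .mm(FBP, p$K_Fba_FBP),
    L_Emp = p$vmax_Emp * .mm(GAP, p$K_Emp_GAP) * .mm(NAD, p$K_Emp_NAD) *
      .mm(ADP, p$K_Emp_ADP) / (1 + (NADH / p$Ki_Emp_NADH)^p$n_Emp_NADH),
    Pyk = p$vmax_Pyk * fr("Pyk") * .mm(PEP, p$K_Pyk_PEP) *
      .mm(ADP, p$K_Pyk_ADP) *
      (p$a0_Pyk + (1 - p$a0_Pyk) * .mm(FBP, p$Ka_Pyk_FBP)),
    Pps = p$vmax_Pps * .mm(PYR, p$K_Pps_PYR) * .mm(ATP, p$K_Pps_ATP),
    PDH = p$vmax_PDH * .mm(PYR, p$K_PDH_PYR) * .mm(NAD, p$K_PDH_NAD) /
      (1 + (NADH / p$Ki_PDH_NADH)^p$n_PDH_NADH),
    Pfl = p$vmax_Pfl * fr("Pfl") * .mm(PYR, p$K_Pfl_PYR),
    G6PDH = p$vmax_G6PDH * fr("G6PDH") * .mm(G6P, p$K_G6PDH_G6P) *
      .mm(NADP, p$K_G6PDH_NADP) /
      (1 + (NADPH / p$Ki_G6PDH_NADPH)^p$n_G6PDH_NADPH),
    PGDH = p$vmax_PGDH * fr("PGDH") * .mm(PG6, p$K_PGDH_PG6) *
      .mm(NADP, p$K_PGDH_NADP),
    Rpe = .rl_rev1(Ru5P, X5P, p$vmax_Rpe, p$K_Rpe, p$K_Rpe, p$Keq_Rpe),
    Rpi = .rl_rev1(Ru5P, R5P, p$vmax_Rpi, p$K_Rpi, p$K_Rpi, p$Keq_Rpi),
    TktA = .rl_rev2(X5P, R5P, S7P, GAP, p$vmax_TktA, p$K_TktA, p$Keq_TktA),
    Tal = .rl_rev2(S7P, GAP, E4P, F6P, p$vmax_Tal, p$K_Tal, p$Keq_Tal),
    TktB = .rl_rev2(X5P, E4P, F6P, GAP, p$vmax_TktB, p$K_TktB, p$Keq_TktB),
    CS = p$vmax_CS * fr("CS") * .mm(AcCoA, p$K_CS_AcCoA) *
      .mm(OAA, p$K_CS_OAA),
    ICDH = p$vmax_ICDH * fr("ICDH") * .mm(ICIT, p$K_ICDH_ICIT) *
      .mm(NADP, p$K_ICDH_NADP),
    aKGDH = p$vmax_aKGDH * fr("aKGDH") * .mm(AKG, p$K_aKGDH_AKG) *
      .mm(NAD, p$K_aKGDH_NAD) * .mm(ADP, 0.3),
    SDH = p$vmax_SDH * fr("SDH") * .mm(SUC, p$K_SDH_SUC) *
      .mm(NAD, p$K_aKGDH_NAD),
    Fum = p$vmax_Fum * .mm(FUM, p$K_Fum_FUM),
    MDH = p$vmax_MDH * fr("MDH") * .mm(MAL, p$K_MDH_MAL) *
      .mm(NAD, p$K_MDH_NAD),
    Icl = p$vmax_Icl * .mm(ICIT, p$K_Icl_ICIT),
    MS = p$vmax_MS * .mm(GLX, p$K_MS_GLX) * .mm(AcCoA, p$K_MS_AcCoA),
    Ppc = p$vmax_Ppc * .mm(PEP, p$K_Ppc_PEP) / (1 + OAA / p$Ki_Ppc_OAA),
    Pck = p$vmax_Pck * .mm(OAA, p$K_Pck_OAA) * .mm(ATP, p$K_Pck_ATP),
    Mez = p$vmax_Mez * .mm(MAL, p$K_Mez_MAL) * .mm(NADP, p$K_Mez_NADP),
    PTACK = p$vmax_PTACK * .mm(AcCoA, p$K_PTACK_AcCoA) *
      .mm(ADP, p$K_PTACK_ADP),
    Acs = p$vmax_Acs * fr("Acs") * .mm(ace, p$K_Acs_ACE) * .mm(ATP, 0.3),
    LDH = p$vmax_LDH * .mm(PYR, p$K_LDH_PYR) *
      NADH^2 / (p$K_LDH_NADH^2 + NADH^2),
    ADH = p$vmax_ADH * .mm(AcCoA, p$K_ADH_AcCoA) *
      NADH^2 / (p$K_ADH_NADH^2 + NADH^2),
    Udh = p$vmax_Udh * .mm(NADPH, p$K_Udh_NADPH) * .mm(NAD, p$K_Udh_NAD),
    NOX = p$vmax_NOX * NADH^p$n_NOX /
      (p$K_NOX_NADH^p$n_NOX + NADH^p$n_NOX),
    XT = 0, Xyi = 0, Xyk = 0,
    OP = 0, ATPase = p$vmax_ATPase * .mm(ATP, p$K_ATPase_ATP),
    AtoB = 0, HMGS = 0, HMGR = 0
  )

  xylm <- s("XYL") / p$MW_XYL * 1000
  v[["XT"]] <- p$vmax_XT * fr("XT") * .mm(ATP, p$K_XT_ATP) * xylm /
    (p$K_XYL + (1 + eiia / p$K_I) * xylm)
  v[["Xyi"]] <- p$vmax_Xyi * fr("Xyi") * .mm(s("XYLin"), p$K_XYLin)
  xu <- s("XYLU")
  v[["Xyk"]] <- p$vmax_Xyk * fr("Xyk") * xu * ATP /
    (p$K_XYLU * p$K_Xyk_ATP + p$K_Xyk_ATP * xu + p$K_XYLU * ATP + xu * ATP)

  if (aerobic) {
    v_resp <- p$vmax_resp * fr("OP") * .mm(NADH, p$K_resp_NADH) *
      .mm(ADP, p$K_resp_ADP)
    v[["OP"]] <- p$PO_ratio * v_resp
  }

  if (mva) {
    v[["AtoB"]] <- p$vmax_AtoB * AcCoA^p$n_AtoB /
      (p$K_AtoB_AcCoA^p$n_AtoB + AcCoA^p$n_AtoB) /
      (1 + s("AcAcCoA") / p$Ki_AtoB_AcAcCoA)
    v[["HMGS"]] <- p$vmax_HMGS * .mm(s("AcAcCoA"), p$K_HMGS_AcAcCoA) *
      .mm(AcCoA, p$K_HMGS_AcCoA) / (1 + s("HMGCoA") / p$Ki_HMGS_HMGCoA)
    v[["HMGR"]] <- p$vmax_HMGR * .mm(s("HMGCoA"), p$K_HMGR_HMGCoA) *
      NADPH^2 / (p$K_HMGR_NADPH^2 + NADPH^2)
  }

  if (length(ko) > 0L) v[ko] <- 0
  v[["Glk"]] <- v[["NPTS"]]   # non-PTS uptake is lumped with glucokinase
  v
}

#' Compute the full flux vector at one state
#'
#' Evaluates every reaction's rate law at the given state, with
#' transcription-factor modulation of the maximum rates, enzyme-level
#' effectors (FBP activation of Pyk, NADPH inhibition of G6PDH, G6P feedback
#' on the PTS as a ptsG-mRNA-stability proxy), inducer exclusion, and the
#' genotype's knockouts (exactly zero flux).
#'
#' @param state named state vector (see [initial_state()]).
#' @param genotype an \code{xf_genotype} object.
#' @param params an \code{xf_params} object.
#' @param aerobic logical; anaerobiosis removes the oxidative-phosphorylation
#'   electron-acceptor capacity (OP = 0) and raises ArcA activity.
#' @param tfs optional precomputed TF activities; computed from the state
#'   when \code{NULL}.
#' @return Named numeric vector of specific rates (mmol/gDCW/h).
#' @export
#' @examples
#' v <- compute_fluxes(initial_state(glc = 4), strain_preset("dpgi"))
#' v[["Pgi"]]  # exactly 0
compute_fluxes <- function(state, genotype = NULL, params = default_params(),
                           aerobic = TRUE, tfs = NULL) {
  if (is.null(genotype)) genotype <- genotype()
  p <- params
  if (is.null(tfs)) tfs <- tf_activities(state, genotype, p, aerobic)
  compiled <- .compile_regulation(regulation_map(), p)
  v <- .flux_core(state, p, .ko_multipliers(genotype), tfs, compiled,
                  aerobic, genotype$mva_pathway)
  if (any(!is.finite(v))) {
    bad <- names(v)[!is.finite(v)]
    stop("non-finite flux for reaction(s) ", paste(bad, collapse = ", "),
         " at state: ", paste(sprintf("%s=%.3g", names(state), state),
                              collapse = ", "), call. = FALSE)
  }
  v
}

#' Specific ATP production rate
#'
#' Signed sum over the ATP-producing and ATP-consuming reactions:
#' \deqn{v_{ATP} = OP + v_{L\_Emp} + v_{Pyk} + v_{PTACK} + v_{\alpha KGDH}
#'  - v_{Glk} - v_{Pfk} - v_{Pps} - v_{Pck} - v_{Acs} - v_{XT} - v_{Xyk}}
#' No clamping is applied here; pathological inputs may give negative values.
#'
#' @param fluxes named flux vector from [compute_fluxes()].
#' @param params unused, kept for call-signature uniformity.
#' @return Specific ATP production rate (mmol/gDCW/h).
#' @export
atp_rate <- function(fluxes, params = NULL) {
  fluxes[["OP"]] + fluxes[["L_Emp"]] + fluxes[["Pyk"]] + fluxes[["PTACK"]] +
    fluxes[["aKGDH"]] - fluxes[["Glk"]] - fluxes[["Pfk"]] - fluxes[["Pps"]] -
    fluxes[["Pck"]] - fluxes[["Acs"]] - fluxes[["XT"]] - fluxes[["Xyk"]]
}

#' Specific NADPH production rate
#'
#' Sum of the NADPH-producing reactions: the oxidative PP pathway (G6PDH,
#' 6PGDH), isocitrate dehydrogenase, and malic enzyme. The first term is
#' switchable to the lumped glycolytic segment via
#' \code{params$nadph_first_term = 0}.
#'
#' @param fluxes named flux vector.
#' @param params an \code{xf_params} object.
#' @return Specific NADPH production rate (mmol/gDCW/h).
#' @export
nadph_rate <- function(fluxes, params = default_params()) {
  first <- if (params$nadph_first_term >= 1) "G6PDH" else "L_Emp"
  fluxes[[first]] + fluxes[["PGDH"]] + fluxes[["ICDH"]] + fluxes[["Mez"]]
}

#' Specific growth rate from the ATP balance
#'
#' Linear growth/ATP coupling with non-competitive acetate inhibition:
#' \deqn{\mu = k_{ATP} \, v_{ATP} \, \frac{k_{ACE}}{k_{ACE} + [ACE]}}
#' reducing to the plain linear coupling at [ACE] = 0. Clamped at 0 from
#' below.
#'
#' @param v_atp specific ATP production rate (mmol/gDCW/h).
#' @param ace extracellular acetate (g/l), >= 0.
#' @param params an \code{xf_params} object.
#' @return Specific growth rate (1/h).
#' @export
growth_rate <- function(v_atp, ace = 0, params = default_params()) {
  stopifnot(ace >= 0)
  max(0, params$k_ATP * v_atp * params$k_ACE / (params$k_ACE + ace))
}
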