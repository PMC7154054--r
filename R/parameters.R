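#' Default kinetic parameter set
#'
#' Returns the full parameter set of the central-carbon-metabolism model:
#' maximum specific rates (\code{vmax_*}, mmol/gDCW/h), Michaelis constants
#' (\code{K_*}, mM), allosteric constants, transcription-factor function
#' constants, and global constants (growth/ATP coupling \code{k_ATP},
#' anabolic NADPH demand \code{k_Anabolism}, acetate growth-inhibition
#' constant \code{k_ACE}, cytoplasmic volume, cofactor moiety totals,
#' biomass precursor demands \code{bm_*} in mmol/gDCW).
#'
#' Every entry carries a provenance flag, either \code{"supplementary"}
#' (value stated by the primary literature source of the model) or
#' \code{"fallback"} (value chosen during calibration of this
#' implementation). Inspect with \code{provenance()}.
#'
#' @return A named list of numeric scalars with class \code{"xf_params"} and
#'   a \code{"provenance"} attribute (named character vector).
#' @seealso [read_params()], [write_params()], [validate_params()]
#' @export
#' @examples
#' p <- default_params()
#' p$k_Anabolism
default_params <- function() {
  p <- list(
    ## ---- global constants -------------------------------------------------
    k_ATP        = 0.0105,   # gDCW/mmol ATP: growth = k_ATP * v_ATP
    k_Anabolism  = 14.849,   # mmol NADPH/gDCW required for cell synthesis
    k_ACE        = 5.0,      # g/l acetate growth-inhibition constant
    vol_cyto     = 0.00247,  # l/gDCW cytoplasmic volume (flux -> mM/h)
    MW_GLC       = 180.16,   # g/mol
    MW_XYL       = 150.13,
    MW_ACE       = 60.05,
    MW_MVA       = 148.16,
    A_total      = 3.5,      # mM, ATP+ADP (AMP held in AMP_const)
    AMP_const    = 0.3,      # mM, constant AMP pool member
    N_total      = 2.0,      # mM, NAD+NADH
    NP_total     = 0.30,     # mM, NADP+NADPH
    PO_ratio     = 1.5,      # ATP per NADH in oxidative phosphorylation
    nadph_first_term = 1,    # 1: first NADPH term is G6PDH; 0: GAPDH reading

    ## ---- PTS glucose transport (G6P feedback = ptsG mRNA stability proxy) --
    vmax_PTS = 13, K_PTS_GLC = 0.05, K_PTS_PEP = 0.1,
    K_PTS_G6P = 6.0, n_PTS_G6P = 4,

    ## ---- non-PTS glucose transporters + glucokinase (lumped) --------------
    vmax_NPTS = 5.5, K_NPTS_GLC = 0.3, K_I_NPTS = 0.15, K_NPTS_G6P = 12,

    ## ---- PTS phosphorelay (quasi-steady-state) ----------------------------
    EIIA_total = 1.0,        # scaled total EIIA pool
    K_EIIA = 0.25,           # PEP/PYR ratio at half phosphorylation

    ## ---- glycolysis / gluconeogenesis -------------------------------------
    vmax_Pgi = 22, K_Pgi_G6P = 1.2, K_Pgi_F6P = 2.0, Keq_Pgi = 0.36,
    vmax_Pfk = 12, K_Pfk_F6P = 0.30, K_Pfk_ATP = 0.15,
    vmax_Fbp = 0.4, K_Fbp_FBP = 0.5,
    vmax_Fba = 8, K_Fba_FBP = 1.5,
    vmax_Emp = 28, K_Emp_GAP = 0.60, K_Emp_NAD = 0.08, K_Emp_ADP = 0.30,
    Ki_Emp_NADH = 1.1, n_Emp_NADH = 6,
    vmax_Pyk = 18, K_Pyk_PEP = 0.60, K_Pyk_ADP = 0.25,
    a0_Pyk = 0.06, Ka_Pyk_FBP = 0.45,   # FBP allosteric activation floor
    vmax_Pps = 0.3, K_Pps_PYR = 0.8, K_Pps_ATP = 0.3,
    vmax_PDH = 10, K_PDH_PYR = 0.6, K_PDH_NAD = 0.10,
    Ki_PDH_NADH = 0.35, n_PDH_NADH = 2,
    vmax_Pfl = 8, K_Pfl_PYR = 1.5,

    ## ---- oxidative pentose phosphate pathway ------------------------------
    vmax_G6PDH = 9.0, K_G6PDH_G6P = 1.2, K_G6PDH_NADP = 0.02,
    Ki_G6PDH_NADPH = 0.13, n_G6PDH_NADPH = 3,
    vmax_PGDH = 10, K_PGDH_PG6 = 0.4, K_PGDH_NADP = 0.02,

    ## ---- non-oxidative pentose phosphate pathway (reversible) -------------
    vmax_Rpe = 30, K_Rpe = 1.0, Keq_Rpe = 1.4,
    vmax_Rpi = 30, K_Rpi = 1.0, Keq_Rpi = 3.0,
    vmax_TktA = 30, K_TktA = 0.5, Keq_TktA = 1.2,
    vmax_Tal  = 30, K_Tal  = 0.5, Keq_Tal  = 1.05,
    vmax_TktB = 30, K_TktB = 0.5, Keq_TktB = 10,

    ## ---- TCA cycle + glyoxylate shunt -------------------------------------
    vmax_CS = 7.0, K_CS_AcCoA = 0.30, K_CS_OAA = 0.07,
    vmax_ICDH = 8.0, K_ICDH_ICIT = 0.30, K_ICDH_NADP = 0.02,
    vmax_aKGDH = 6.0, K_aKGDH_AKG = 0.5, K_aKGDH_NAD = 0.10,
    vmax_SDH = 8.0, K_SDH_SUC = 0.5,
    vmax_Fum = 12, K_Fum_FUM = 0.5,
    vmax_MDH = 10, K_MDH_MAL = 0.8, K_MDH_NAD = 0.10,
    vmax_Icl = 0.6, K_Icl_ICIT = 1.0,
    vmax_MS = 0.6, K_MS_GLX = 0.5, K_MS_AcCoA = 0.3,

    ## ---- anaplerosis ------------------------------------------------------
    vmax_Ppc = 8.0, K_Ppc_PEP = 0.3, Ki_Ppc_OAA = 1.0,
    vmax_Pck = 0.3, K_Pck_OAA = 0.7, K_Pck_ATP = 0.3,
    vmax_Mez = 0.5, K_Mez_MAL = 1.5, K_Mez_NADP = 0.02,

    ## ---- acetate / fermentation -------------------------------------------
    vmax_PTACK = 6.5, K_PTACK_AcCoA = 0.6, K_PTACK_ADP = 0.3,
    vmax_Acs = 0.8, K_Acs_ACE = 0.6,      # K in mM extracellular acetate
    vmax_LDH = 16, K_LDH_PYR = 0.6, K_LDH_NADH = 0.40,
    vmax_ADH = 16, K_ADH_AcCoA = 0.3, K_ADH_NADH = 0.40,

    ## ---- non-respiratory NADH turnover (futile cycles, detox) -------------
    vmax_NOX = 3.0, K_NOX_NADH = 1.5, n_NOX = 4,

    ## ---- soluble transhydrogenase (UdhA, NADPH -> NADH) -------------------
    vmax_Udh = 3.0, K_Udh_NADPH = 0.15, K_Udh_NAD = 0.2,

    ## ---- respiration / oxidative phosphorylation --------------------------
    vmax_resp = 60, K_resp_NADH = 0.10, K_resp_ADP = 0.25,
    vmax_ATPase = 20, K_ATPase_ATP = 1.0,

    ## ---- xylose transport and assimilation --------------------------------
    vmax_XT = 9.0, K_XYL = 0.3, K_I = 0.15, K_XT_ATP = 0.1,        # K_XYL mM ext; K_I vs EIIA
    vmax_Xyi = 14, K_XYLin = 1.2,
    vmax_Xyk = 14, K_XYLU = 1.0, K_Xyk_ATP = 0.3,

    ## ---- mevalonate pathway (Enterococcus faecalis AtoB/HMGS/HMGR) --------
    vmax_AtoB = 3.0, K_AtoB_AcCoA = 0.5, n_AtoB = 2,
    vmax_HMGS = 3.0, K_HMGS_AcAcCoA = 0.25, K_HMGS_AcCoA = 0.5,
    Ki_HMGS_HMGCoA = 0.4, Ki_AtoB_AcAcCoA = 0.4,
    vmax_HMGR = 3.0, K_HMGR_HMGCoA = 0.25, K_HMGR_NADPH = 0.20,

    ## ---- transcription-factor activity functions --------------------------
    cAMP_max = 10,                         # microM scale, reporting only
    K_Crp_phi = 0.45, n_Crp = 4,           # cAMP-Crp vs EIIA-P fraction
    K_Cra_FBP = 1.0, n_Cra = 2,            # Cra repressed by FBP
    K_XylR = 0.5, n_XylR = 1,              # XylR vs intracellular xylose
    K_ArcA = 0.60, n_ArcA = 3,             # ArcA vs NADH/NAD ratio (aerobic)
    ArcA_anaerobic = 0.95,                 # ArcA activity under anaerobiosis

    ## ---- wild-type reference TF activities (f(TF) normalization) ----------
    ref_Crp = 0.05, ref_Cra = 0.08, ref_ArcA = 0.08, ref_XylR = 0.05,

    ## ---- biomass precursor demands (mmol/gDCW) ----------------------------
    bm_G6P = 0.205, bm_F6P = 0.071, bm_R5P = 0.898, bm_E4P = 0.361,
    bm_GAP = 0.129, bm_PEP = 0.720, bm_PYR = 2.830, bm_AcCoA = 3.748,
    bm_OAA = 1.787, bm_AKG = 1.079,
    bm_ATP = 80                            # anabolic ATP demand, mmol/gDCW
  )
  prov <- rep("fallback", length(p))
  names(prov) <- names(p)
  prov[c("k_Anabolism", "ArcA_anaerobic")] <- "supplementary"
  structure(p, provenance = prov, class = "xf_params")
}

#' Provenance flags of a parameter set
#'
#' @param params an \code{xf_params} object.
#' @return Named character vector, one of \code{"supplementary"} or
#'   \code{"fallback"} per entry.
#' @export
provenance <- function(params) {
  attr(params, "provenance")
}

#' Validate a parameter set
#'
#' Checks completeness against the default template, strict positivity of all
#' Michaelis constants and maximum rates, Hill coefficients >= 1, and the
#' anabolic NADPH demand when flagged as literature-sourced.
#'
#' @param params an \code{xf_params} object.
#' @return \code{params}, invisibly; stops with an informative error on the
#'   first violated constraint.
#' @export
validate_params <- function(params) {
  template <- default_params()
  missing <- setdiff(names(template), names(params))
  if (length(missing) > 0L) {
    stop("parameter set incomplete; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(params[names(template)])
  pos <- grep("^(vmax_|K_|Ki_|Ka_)", names(vals), value = TRUE)
  if (any(vals[pos] <= 0)) {
    bad <- pos[vals[pos] <= 0]
    stop("parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hill <- grep("^n_", names(vals), value = TRUE)
  if (any(vals[hill] < 1)) {
    stop("Hill coefficients must be >= 1: ",
         paste(hill[vals[hill] < 1], collapse = ", "), call. = FALSE)
  }
  prov <- provenance(params)
  if (!is.null(prov) && identical(prov[["k_Anabolism"]], "supplementary") &&
      abs(params$k_Anabolism - 14.849) > 1e-9) {
    stop("k_Anabolism flagged 'supplementary' must equal 14.849 mmol/gDCW",
         call. = FALSE)
  }
  invisible(params)
}

#' Read a parameter file
#'
#' Parameter files are YAML with two top-level keys: \code{values} (name ->
#' number) and \code{provenance} (name -> "supplementary"/"fallback").
#' Required global constants (\code{k_ATP}, \code{k_Anabolism}, \code{k_ACE})
#' and the xylose-subsystem constants (\code{K_XYL}, \code{K_I},
#' \code{K_XYLin}, \code{K_XYLU}, \code{K_Xyk_ATP}) must be present.
#'
#' @param path path to a YAML parameter file.
#' @return A validated \code{xf_params} object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed parameter file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(doc) || is.null(doc$values)) {
    stop("parameter file must contain a 'values' mapping", call. = FALSE)
  }
  required <- c("k_ATP", "k_Anabolism", "k_ACE",
                "K_XYL", "K_I", "K_XYLin", "K_XYLU", "K_Xyk_ATP")
  missing <- setdiff(required, names(doc$values))
  if (length(missing) > 0L) {
    stop("parameter file missing required entries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- default_params()
  prov <- attr(p, "provenance")
  for (nm in names(doc$values)) {
    p[[nm]] <- as.numeric(doc$values[[nm]])
  }
  if (!is.null(doc$provenance)) {
    pf <- unlist(doc$provenance)
    bad <- setdiff(unique(pf), c("supplementary", "fallback"))
    if (length(bad) > 0L) {
      stop("unknown provenance flag(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    prov[names(pf)] <- pf
  }
  attr(p, "provenance") <- prov
  class(p) <- "xf_params"
  validate_params(p)
  p
}

#' Write a parameter file
#'
#' @param params an \code{xf_params} object.
#' @param path output path (YAML).
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  prov <- provenance(params)
  doc <- list(values = lapply(params, as.vector),
              provenance = as.list(prov))
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' @export
print.xf_params <- function(x, ...) {
  prov <- provenance(x)
  cat("<xf_params> ", length(x), " entries (",
      sum(prov == "supplementary"), " supplementary, ",
      sum(prov == "fallback"), " fallback)\n", sep = "")
  invisible(x)
}
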