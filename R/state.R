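# State vector layout. Intracellular metabolites in mM; extracellular
# substrates/products in g/l; biomass in gDCW/l. Cofactors use moiety
# reduction: ATP, NADH, NADPH are integrated, their partners follow from the
# conserved totals (A_total + AMP_const, N_total, NP_total).

.xf_intracellular <- c(
  "G6P", "F6P", "FBP", "GAP", "PEP", "PYR", "AcCoA", "PG6",
  "Ru5P", "X5P", "R5P", "S7P", "E4P",
  "ICIT", "AKG", "SUC", "FUM", "MAL", "OAA", "GLX",
  "XYLin", "XYLU", "ATP", "NADH", "NADPH", "AcAcCoA", "HMGCoA"
)

.xf_extracellular <- c("GLC", "XYL", "ACE", "MVA", "X")

.xf_species <- c(.xf_intracellular, .xf_extracellular)

#' Initial network state
#'
#' Builds the full state vector for a simulation: typical exponential-phase
#' intracellular pools plus the extracellular medium composition. All
#' concentrations are non-negative; cofactor entries must stay within their
#' conserved moiety totals.
#'
#' @param glc,xyl,ace,mva initial extracellular concentrations (g/l).
#' @param biomass initial biomass (gDCW/l).
#' @param params an \code{xf_params} object (for moiety totals).
#' @return Named numeric vector over all model species.
#' @export
#' @examples
#' s <- initial_state(glc = 5, xyl = 5)
#' s[["GLC"]]
initial_state <- function(glc = 4, xyl = 0, ace = 0, mva = 0,
                          biomass = 0.01, params = default_params()) {
  stopifnot(glc >= 0, xyl >= 0, ace >= 0, mva >= 0, biomass >= 0)
  s <- c(
    G6P = 1.0, F6P = 0.35, FBP = 1.5, GAP = 0.25, PEP = 0.4, PYR = 1.5,
    AcCoA = 0.5, PG6 = 0.3, Ru5P = 0.1, X5P = 0.15, R5P = 0.1,
    S7P = 0.1, E4P = 0.08,
    ICIT = 0.2, AKG = 0.5, SUC = 0.5, FUM = 0.3, MAL = 1.0, OAA = 0.1,
    GLX = 0.01, XYLin = 0, XYLU = 0,
    ATP = 2.5, NADH = 0.08, NADPH = 0.12,
    AcAcCoA = 0, HMGCoA = 0,
    GLC = glc, XYL = xyl, ACE = ace, MVA = mva, X = biomass
  )
  stopifnot(identical(names(s), .xf_species))
  s[["ATP"]] <- min(s[["ATP"]], params$A_total - 1e-6)
  s
}

# Derived cofactor partners (moiety reduction).
.cofactor_partners <- function(state, p) {
  list(
    ADP  = max(p$A_total - state[["ATP"]], 1e-9),
    AMP  = p$AMP_const,
    NAD  = max(p$N_total - state[["NADH"]], 1e-9),
    NADP = max(p$NP_total - state[["NADPH"]], 1e-9)
  )
}

#' PTS phosphorelay quasi-steady state
#'
#' Phosphorylated-EIIA fraction as a saturating, monotone-increasing function
#' of the PEP/PYR ratio. Unphosphorylated EIIA mediates inducer exclusion of
#' non-glucose transporters.
#'
#' @param state named state vector.
#' @param params an \code{xf_params} object.
#' @return List with \code{phi} (phosphorylated fraction in [0,1]) and
#'   \code{EIIA} (unphosphorylated EIIA concentration, scaled units).
#' @export
eiia_state <- function(state, params) {
  # small offsets keep the ratio defined as both pools empty (a starving
  # cell relaxes toward phosphorylated EIIA, i.e. the hunger signal)
  r <- (state[["PEP"]] + 0.01) / (state[["PYR"]] + 0.01)
  phi <- r / (params$K_EIIA + r)
  list(phi = phi, EIIA = params$EIIA_total * (1 - phi))
}
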