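#' Transcription-factor regulation map
#'
#' The (TF, target reaction, sign) triples used to modulate maximum reaction
#' rates: cAMP-Crp and XylR activate the xylose genes (XT, Xyi, Xyk),
#' cAMP-Crp activates the non-PTS glucose transporters (npts) and acetate
#' re-assimilation (acs), Cra represses pykF and the oxidative PP genes
#' (zwf, gnd), and ArcA represses the TCA-cycle genes and the respiratory
#' chain (nuo/cyo) while activating pfl. Each edge carries a basal capacity
#' \code{c0} for the fully repressed (repression) or uninduced (activation)
#' limit.
#'
#' @return data.frame with columns \code{tf}, \code{target}, \code{sign}
#'   (\code{"+"} or \code{"-"}) and \code{c0}.
#' @export
regulation_map <- function() {
  edges <- rbind(
    c("Crp",  "XT",    "+", 0.02),
    c("XylR", "XT",    "+", 0.05),
    c("Crp",  "Xyi",   "+", 0.02),
    c("XylR", "Xyi",   "+", 0.05),
    c("Crp",  "Xyk",   "+", 0.02),
    c("XylR", "Xyk",   "+", 0.05),
    c("Crp",  "NPTS",  "+", 0.08),
    c("Crp",  "Acs",   "+", 0.10),
    c("Cra",  "Pyk",   "-", 0.30),
    c("Cra",  "G6PDH", "-", 0.60),
    c("Cra",  "PGDH",  "-", 0.60),
    c("ArcA", "CS",    "-", 0.05),
    c("ArcA", "ICDH",  "-", 0.05),
    c("ArcA", "aKGDH", "-", 0.05),
    c("ArcA", "SDH",   "-", 0.05),
    c("ArcA", "MDH",   "-", 0.05),
    c("ArcA", "OP",    "-", 0.40),
    c("ArcA", "Pfl",   "+", 0.03)
  )
  data.frame(tf = edges[, 1], target = edges[, 2], sign = edges[, 3],
             c0 = as.numeric(edges[, 4]), stringsAsFactors = FALSE)
}

#' Transcription-factor activities
#'
#' Computes the activities (in [0,1]) of cAMP-Crp, Cra, ArcA and XylR from
#' the metabolic state:
#' \itemize{
#'   \item cAMP-Crp rises with the PEP/PYR ratio through the PTS
#'     phosphorelay (phosphorylated EIIA stimulates adenylate cyclase);
#'   \item Cra is repressed by fructose-1,6-bisphosphate;
#'   \item ArcA follows the NADH/NAD redox ratio under aerobiosis and is
#'     pinned near 1 anaerobically;
#'   \item XylR rises with intracellular xylose.
#' }
#' Genotype overrides (e.g. ArcA overexpression) take precedence exactly.
#'
#' @param state named state vector (see [initial_state()]).
#' @param genotype an \code{xf_genotype} object (see [genotype()]).
#' @param params an \code{xf_params} object.
#' @param aerobic logical culture flag.
#' @return Named numeric vector \code{c(Crp=, Cra=, ArcA=, XylR=)}, each in
#'   [0,1], with attribute \code{"cAMP"} (reporting-scale cAMP level).
#' @export
#' @examples
#' tfs <- tf_activities(initial_state(glc = 4), genotype(), default_params())
tf_activities <- function(state, genotype = NULL, params = default_params(),
                          aerobic = TRUE) {
  p <- params
  for (nm in c("K_Crp_phi", "n_Crp", "K_Cra_FBP", "n_Cra",
               "K_ArcA", "n_ArcA", "K_XylR", "n_XylR")) {
    if (is.null(p[[nm]])) {
      stop("missing TF constant '", nm, "' for TF activity functions",
           call. = FALSE)
    }
  }
  phi <- eiia_state(state, p)$phi
  crp <- phi^p$n_Crp / (p$K_Crp_phi^p$n_Crp + phi^p$n_Crp)
  fbp <- max(state[["FBP"]], 0)
  cra <- p$K_Cra_FBP^p$n_Cra / (p$K_Cra_FBP^p$n_Cra + fbp^p$n_Cra)
  if (aerobic) {
    rr <- state[["NADH"]] / max(p$N_total - state[["NADH"]], 1e-9)
    arca <- rr^p$n_ArcA / (p$K_ArcA^p$n_ArcA + rr^p$n_ArcA)
  } else {
    arca <- p$ArcA_anaerobic
  }
  xi <- max(state[["XYLin"]], 0)
  xylr <- xi^p$n_XylR / (p$K_XylR^p$n_XylR + xi^p$n_XylR)
  act <- c(Crp = crp, Cra = cra, ArcA = arca, XylR = xylr)
  act <- pmin(pmax(act, 0), 1)
  if (!is.null(genotype) && length(genotype$tf_overrides) > 0L) {
    ov <- genotype$tf_overrides
    act[names(ov)] <- ov
  }
  attr(act, "cAMP") <- p$cAMP_max * phi
  act
}

# Single-edge regulation factor. Activation: f = c0 + (1-c0)*TF (f(1)=1).
# Repression: f = c0 + c1*(1-TF) with c1 = (1-c0)/(1-ref), so f(ref)=1 and
# f(1)=c0; ref is the wild-type reference activity of that TF.
.reg_factor <- function(tf_name, sign, c0, tf_value, p) {
  if (sign == "+") {
    c0 + (1 - c0) * tf_value
  } else {
    ref <- switch(tf_name,
                  Crp = p$ref_Crp, Cra = p$ref_Cra,
                  ArcA = p$ref_ArcA, XylR = p$ref_XylR, 0)
    c1 <- (1 - c0) / (1 - ref)
    max(c0 + c1 * (1 - tf_value), 0)
  }
}

#' Transcription-factor modulated maximum rate
#'
#' Scales a reaction's original maximum rate \code{vmax'} by the product of
#' its transcription-factor regulation factors: capacity is non-decreasing in
#' each activating TF and non-increasing in each repressing TF; unregulated
#' reactions return \code{vmax'} unchanged.
#'
#' @param reaction reaction name (e.g. \code{"XT"}, \code{"CS"}).
#' @param tfs TF activity vector from [tf_activities()].
#' @param reg regulation map (default [regulation_map()]).
#' @param params an \code{xf_params} object.
#' @return Non-negative rate capacity (mmol/gDCW/h).
#' @export
regulated_vmax <- function(reaction, tfs, reg = regulation_map(),
                           params = default_params()) {
  vkey <- if (reaction == "Emp") "vmax_Emp" else paste0("vmax_", reaction)
  vmax <- switch(reaction,
                 OP = params$vmax_resp * params$PO_ratio,
                 params[[vkey]])
  if (is.null(vmax)) stop("unknown reaction: ", reaction, call. = FALSE)
  f <- regulation_factor(reaction, tfs, reg, params)
  vmax * f
}

#' Combined regulation factor f(TF) for one reaction
#'
#' @inheritParams regulated_vmax
#' @return Scalar f >= 0; 1 for unregulated reactions.
#' @export
regulation_factor <- function(reaction, tfs, reg = regulation_map(),
                              params = default_params()) {
  rows <- reg[reg$target == reaction, , drop = FALSE]
  if (nrow(rows) == 0L) return(1)
  f <- 1
  for (i in seq_len(nrow(rows))) {
    tf <- rows$tf[i]
    if (!tf %in% names(tfs)) {
      stop("TF '", tf, "' required for reaction '", reaction,
           "' not present in activities", call. = FALSE)
    }
    f <- f * .reg_factor(tf, rows$sign[i], rows$c0[i], tfs[[tf]], params)
  }
  f
}
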