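#' Gene-to-reaction map
#'
#' Knockouts address reactions through this explicit map. Lumped reactions
#' are disabled as a whole (e.g. \code{ackA} removes the combined
#' Pta-Ack acetate pathway PTACK).
#'
#' @return Named character vector: gene -> reaction.
#' @export
gene_reaction_map <- function() {
  c(pgi = "Pgi", ptsG = "PTS", pfl = "Pfl", ackA = "PTACK",
    zwf = "G6PDH", gnd = "PGDH", pykF = "Pyk", ppc = "Ppc",
    aceA = "Icl", maeB = "Mez", acs = "Acs", udhA = "Udh",
    xylA = "Xyi", xylB = "Xyk", xylE = "XT")
}

#' Construct a genotype
#'
#' @param knockouts character vector of gene names (see
#'   [gene_reaction_map()]).
#' @param tf_overrides named numeric vector pinning TF activities in [0,1]
#'   (names among Crp, Cra, ArcA, XylR).
#' @param mva_pathway logical; enable the heterologous mevalonate pathway
#'   (AtoB, HMGS, HMGR from AcCoA).
#' @return An \code{xf_genotype} object.
#' @export
#' @examples
#' g <- genotype(knockouts = "pgi")
genotype <- function(knockouts = character(), tf_overrides = numeric(),
                     mva_pathway = FALSE) {
  map <- gene_reaction_map()
  unknown <- setdiff(knockouts, names(map))
  if (length(unknown) > 0L) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "),
         "; supported genes: ", paste(names(map), collapse = ", "),
         call. = FALSE)
  }
  if (length(tf_overrides) > 0L) {
    if (is.null(names(tf_overrides)) ||
        !all(names(tf_overrides) %in% c("Crp", "Cra", "ArcA", "XylR"))) {
      stop("tf_overrides must be named with TFs among Crp, Cra, ArcA, XylR",
           call. = FALSE)
    }
    if (any(tf_overrides < 0 | tf_overrides > 1)) {
      stop("TF override activities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(knockouts = sort(unique(knockouts)),
                 tf_overrides = tf_overrides,
                 mva_pathway = isTRUE(mva_pathway)),
            class = "xf_genotype")
}

#' Knock out a gene
#'
#' Returns a genotype in which the reaction mapped to \code{gene} carries
#' exactly zero flux. Idempotent.
#'
#' @param geno an \code{xf_genotype} object.
#' @param gene gene name.
#' @return Modified \code{xf_genotype}.
#' @export
knockout <- function(geno, gene) {
  genotype(knockouts = c(geno$knockouts, gene),
           tf_overrides = geno$tf_overrides,
           mva_pathway = geno$mva_pathway)
}

#' Pin a transcription factor's activity (overexpression/deletion proxy)
#'
#' Models TF overexpression as pinning its activity to a fixed level in
#' [0,1] for all downstream computations (no promoter dynamics).
#'
#' @param geno an \code{xf_genotype} object.
#' @param tf TF name among Crp, Cra, ArcA, XylR.
#' @param level fixed activity in [0,1].
#' @return Modified \code{xf_genotype}.
#' @export
#' @examples
#' g <- overexpress_tf(genotype("pgi"), "ArcA", 0.95)
overexpress_tf <- function(geno, tf, level) {
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level > 1) {
    stop("TF activity level must be a single number in [0, 1]", call. = FALSE)
  }
  ov <- geno$tf_overrides
  ov[tf] <- level
  genotype(knockouts = geno$knockouts, tf_overrides = ov,
           mva_pathway = geno$mva_pathway)
}

#' Enable the heterologous mevalonate pathway
#'
#' Adds the three-step route from acetyl-CoA: AtoB (2 AcCoA -> AcAcCoA),
#' HMGS (AcAcCoA + AcCoA -> HMG-CoA), HMGR (HMG-CoA + 2 NADPH -> mevalonate,
#' exported). The kinetic constants must be present in \code{params}.
#'
#' @param geno an \code{xf_genotype} object.
#' @param params an \code{xf_params} object carrying the MVA constants.
#' @return Modified \code{xf_genotype} with \code{mva_pathway = TRUE}.
#' @export
add_mva_pathway <- function(geno, params = default_params()) {
  need <- c("vmax_AtoB", "K_AtoB_AcCoA", "vmax_HMGS", "K_HMGS_AcAcCoA",
            "K_HMGS_AcCoA", "vmax_HMGR", "K_HMGR_HMGCoA", "K_HMGR_NADPH")
  missing <- need[vapply(need, function(nm) is.null(params[[nm]]), logical(1))]
  if (length(missing) > 0L) {
    stop("missing mevalonate-pathway constants: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  genotype(knockouts = geno$knockouts, tf_overrides = geno$tf_overrides,
           mva_pathway = TRUE)
}

#' Strain presets
#'
#' The strains used throughout the analyses: wild type, single-gene
#' knockouts, and mevalonate-producing derivatives (the
#' \code{MVA_dpgi_arcA} redesign pins ArcA activity at 0.95).
#'
#' @param name one of \code{"WT"}, \code{"dpgi"}, \code{"dptsG"},
#'   \code{"dpfl"}, \code{"dack"}, \code{"MVA_WT"}, \code{"MVA_dpgi"},
#'   \code{"MVA_dpgi_arcA"}.
#' @return An \code{xf_genotype} object.
#' @export
#' @examples
#' strain_preset("dpgi")
strain_preset <- function(name = c("WT", "dpgi", "dptsG", "dpfl", "dack",
                                   "MVA_WT", "MVA_dpgi", "MVA_dpgi_arcA")) {
  name <- match.arg(name)
  switch(name,
    WT    = genotype(),
    dpgi  = genotype("pgi"),
    dptsG = genotype("ptsG"),
    dpfl  = genotype("pfl"),
    dack  = genotype("ackA"),
    MVA_WT   = genotype(mva_pathway = TRUE),
    MVA_dpgi = genotype("pgi", mva_pathway = TRUE),
    MVA_dpgi_arcA = genotype("pgi", tf_overrides = c(ArcA = 0.95),
                             mva_pathway = TRUE)
  )
}

#' @export
print.xf_genotype <- function(x, ...) {
  cat("<xf_genotype> knockouts: ",
      if (length(x$knockouts)) paste(x$knockouts, collapse = ", ") else "none",
      "; TF overrides: ",
      if (length(x$tf_overrides)) {
        paste(names(x$tf_overrides), "=", x$tf_overrides, collapse = ", ")
      } else "none",
      "; MVA pathway: ", x$mva_pathway, "\n", sep = "")
  invisible(x)
}
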