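#' Write a trajectory to delimited files
#'
#' Writes three CSV tables under \code{dir}: \code{states.csv} (time plus
#' every species), \code{fluxes.csv} (time plus every reaction rate) and
#' \code{scalars.csv} (time, growth rate, v_ATP, v_NADPH, TF activities,
#' EIIA-P fraction, cAMP), plus a \code{metadata.yml} sidecar with units,
#' scenario, genotype and solver settings. Values are written at full double
#' precision so the round trip is lossless.
#'
#' @param trajectory an \code{xf_trajectory}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_trajectory <- function(trajectory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m) {
    df <- as.data.frame(m)
    df[] <- lapply(df, function(col) sprintf("%.17g", col))
    df
  }
  states <- cbind(time = trajectory$times, trajectory$states)
  fluxes <- cbind(time = trajectory$times, trajectory$fluxes)
  scalars <- cbind(time = trajectory$times, mu = trajectory$mu,
                   v_ATP = trajectory$v_ATP, v_NADPH = trajectory$v_NADPH,
                   trajectory$tfs, EIIAP = trajectory$EIIAP,
                   cAMP = trajectory$cAMP)
  utils::write.csv(fmt(states), file.path(dir, "states.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(fluxes), file.path(dir, "fluxes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(scalars), file.path(dir, "scalars.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    units = list(time = "h", intracellular = "mM",
                 extracellular = "g/l", biomass = "gDCW/l",
                 fluxes = "mmol/gDCW/h", mu = "1/h"),
    scenario = unclass(trajectory$scenario),
    genotype = list(knockouts = trajectory$genotype$knockouts,
                    tf_overrides = as.list(trajectory$genotype$tf_overrides),
                    mva_pathway = trajectory$genotype$mva_pathway),
    cultivation_time = trajectory$T,
    status = trajectory$status)
  yaml::write_yaml(meta, file.path(dir, "metadata.yml"))
  invisible(dir)
}

#' Read back a trajectory written by [write_trajectory()]
#'
#' @param dir directory containing the CSV tables.
#' @return List with \code{states}, \code{fluxes}, \code{scalars}
#'   data.frames and \code{metadata}.
#' @export
read_trajectory <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  list(states = rd("states.csv"), fluxes = rd("fluxes.csv"),
       scalars = rd("scalars.csv"),
       metadata = yaml::read_yaml(file.path(dir, "metadata.yml")))
}

#' Read a measured-flux table
#'
#' Two-column delimited text: reaction name and flux (mmol/gDCW/h).
#' Whitespace- or comma-delimited; lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return data.frame with columns \code{reaction}, \code{flux}.
#' @export
read_flux_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[,\t ]+")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop("malformed flux table '", path, "' at line ", bad[1], call. = FALSE)
  }
  data.frame(reaction = vapply(parts, `[[`, "", 1L),
             flux = as.numeric(vapply(parts, `[[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Write a measured-flux table
#'
#' @param fluxes data.frame with columns \code{reaction}, \code{flux}, or a
#'   named flux vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_flux_table <- function(fluxes, path) {
  if (!is.data.frame(fluxes)) {
    fluxes <- data.frame(reaction = names(fluxes),
                         flux = as.numeric(fluxes))
  }
  writeLines(c("# reaction\tflux (mmol/gDCW/h)",
               sprintf("%s\t%.17g", fluxes$reaction, fluxes$flux)), path)
  invisible(path)
}

#' Generate a noisy measured-flux fixture
#'
#' Simulates a reference state with the given genotype, perturbs the flux
#' vector with i.i.d. Gaussian noise (sigma = \code{noise} times the flux
#' range) under a fixed seed, and writes it as a measured-flux table. This
#' makes the correlation utility testable without literature data; the
#' output is synthetic, not an experimental dataset.
#'
#' @param path output path.
#' @param seed random seed.
#' @param genotype an \code{xf_genotype} object.
#' @param params an \code{xf_params} object.
#' @param noise noise standard deviation as a fraction of the flux range.
#' @return Invisible list with \code{simulated} (clean vector) and
#'   \code{measured} (perturbed data.frame).
#' @export
make_flux_fixture <- function(path, seed = 1, genotype = NULL,
                              params = default_params(), noise = 0.05) {
  if (is.null(genotype)) genotype <- genotype()
  sc <- culture_scenario(glc = 5, xyl = 5, n_out = 120, horizon = 24)
  tr <- simulate_batch(sc, genotype, params)
  k <- .exp_phase_index(tr)
  sim <- tr$fluxes[k, ]
  set.seed(seed)
  meas <- sim + stats::rnorm(length(sim), 0,
                             noise * (max(sim) - min(sim)))
  df <- data.frame(reaction = names(sim), flux = as.numeric(meas))
  write_flux_table(df, path)
  invisible(list(simulated = sim, measured = df))
}
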