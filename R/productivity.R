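# Trapezoid on the solver's dense grid; the grid (scenario n_out) is chosen
# so the quadrature error is well below 0.1% (verified as a property).
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Total NADPH produced over a batch culture
#'
#' \deqn{\int_0^T v_{NADPH}(t)\, X(t)\, dt} by trapezoidal quadrature on the
#' trajectory's dense output grid, restricted to the cultivation time T.
#'
#' @param trajectory an \code{xf_trajectory} from [simulate_batch()].
#' @return Total NADPH produced (mmol per liter of culture).
#' @export
total_nadph <- function(trajectory) {
  keep <- trajectory$times <= trajectory$T + 1e-12
  unname(.trapz(trajectory$times[keep],
                trajectory$v_NADPH[keep] * trajectory$states[keep, "X"]))
}

#' Anabolic NADPH demand
#'
#' NADPH consumed for cell synthesis over a batch culture:
#' \code{k_Anabolism * X(T)} with \code{k_Anabolism} = 14.849 mmol/gDCW.
#'
#' @param final_biomass final cell concentration X(T) (gDCW/l).
#' @param params an \code{xf_params} object.
#' @return Demand in mmol per liter of culture.
#' @export
anabolic_demand <- function(final_biomass, params = default_params()) {
  stopifnot(final_biomass >= 0)
  params$k_Anabolism * final_biomass
}

#' NADPH productivity of a batch culture
#'
#' Available NADPH (total produced minus anabolic demand) divided by the
#' cultivation time T. Negative values are returned unclamped: they signal
#' that growth demand exceeded production and the deficit must be covered
#' by transhydrogenase.
#'
#' @param trajectory an \code{xf_trajectory}.
#' @param params an \code{xf_params} object.
#' @return Productivity (mmol/l/h).
#' @export
nadph_productivity <- function(trajectory, params = trajectory$params) {
  T <- trajectory$T
  if (T <= 0) stop("cultivation time is zero; productivity undefined",
                   call. = FALSE)
  n <- which(trajectory$times <= T + 1e-12)
  XT <- unname(trajectory$states[n[length(n)], "X"])
  unname((total_nadph(trajectory) - anabolic_demand(XT, params)) / T)
}

# exponential-phase specific rates: evaluated at the time of maximum mu,
# ignoring the initial adaptation transient
.exp_phase_index <- function(trajectory, skip_frac = 0.02) {
  t0 <- max(trajectory$times) * skip_frac
  idx <- which(trajectory$times >= t0)
  idx[which.max(trajectory$mu[idx])]
}

#' Xylose-content design scan
#'
#' For each xylose content c on the grid, runs an aerobic batch culture with
#' glucose (1 - c/100) x total and xylose (c/100) x total (g/l) and collects
#' the performance metrics: exponential-phase growth rate and specific NADPH
#' production rate, total NADPH produced, anabolic demand, NADPH
#' availability and productivity, final biomass, final mevalonate titer and
#' cultivation time. Deterministic given the parameters.
#'
#' @param preset strain preset name (see [strain_preset()]) or an
#'   \code{xf_genotype}.
#' @param total_substrate total glucose + xylose concentration (g/l).
#' @param grid xylose contents in percent, within [0, 100].
#' @param params an \code{xf_params} object.
#' @param biomass initial biomass (gDCW/l).
#' @param horizon batch horizon (h).
#' @param n_out dense-output resolution per run.
#' @return An \code{xf_scan} object: \code{table} (data.frame, one row per
#'   content) and \code{argmax} (named list of optimal contents per metric;
#'   ties broken toward the lower content).
#' @export
#' @examples
#' \donttest{
#' sc <- xylose_scan("dpgi", total_substrate = 10, grid = seq(0, 100, 20))
#' sc$argmax$nadph_productivity
#' }
xylose_scan <- function(preset, total_substrate = 10,
                        grid = seq(0, 100, by = 1),
                        params = default_params(), biomass = 0.01,
                        horizon = 48, n_out = 400) {
  stopifnot(total_substrate > 0, all(grid >= 0 & grid <= 100))
  geno <- if (inherits(preset, "xf_genotype")) preset else strain_preset(preset)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    c_i <- grid[i]
    sc <- culture_scenario(glc = (1 - c_i / 100) * total_substrate,
                           xyl = c_i / 100 * total_substrate,
                           biomass = biomass, horizon = horizon,
                           n_out = n_out)
    row <- tryCatch({
      tr <- simulate_batch(sc, geno, params)
      k <- .exp_phase_index(tr)
      nT <- max(which(tr$times <= tr$T + 1e-12))
      tot <- total_nadph(tr)
      dem <- anabolic_demand(tr$states[nT, "X"], params)
      data.frame(
        content = c_i, ok = TRUE,
        mu_exp = tr$mu[k], v_nadph_exp = tr$v_NADPH[k],
        v_nadph_opp_exp = tr$fluxes[k, "G6PDH"] + tr$fluxes[k, "PGDH"],
        v_nadph_icdh_exp = tr$fluxes[k, "ICDH"],
        total_nadph = tot, anabolic_demand = dem,
        nadph_availability = tot - dem,
        nadph_productivity = (tot - dem) / tr$T,
        final_biomass = tr$states[nT, "X"],
        final_mva = tr$states[nT, "MVA"],
        cultivation_time = tr$T)
    }, error = function(e) {
      data.frame(content = c_i, ok = FALSE, mu_exp = NA_real_,
                 v_nadph_exp = NA_real_, v_nadph_opp_exp = NA_real_,
                 v_nadph_icdh_exp = NA_real_, total_nadph = NA_real_,
                 anabolic_demand = NA_real_, nadph_availability = NA_real_,
                 nadph_productivity = NA_real_, final_biomass = NA_real_,
                 final_mva = NA_real_, cultivation_time = NA_real_)
    })
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  amax <- function(metric) {
    v <- tab[[metric]]
    if (all(is.na(v))) return(NA_real_)
    tab$content[which.max(replace(v, is.na(v), -Inf))]  # first max = lowest
  }
  structure(list(
    table = tab,
    total_substrate = total_substrate,
    genotype = geno,
    argmax = list(nadph_productivity = amax("nadph_productivity"),
                  nadph_availability = amax("nadph_availability"),
                  final_mva = amax("final_mva"),
                  mu_exp = amax("mu_exp"))),
    class = "xf_scan")
}

#' @export
print.xf_scan <- function(x, ...) {
  cat("<xf_scan> ", nrow(x$table), " contents, total substrate ",
      x$total_substrate, " g/l\n", sep = "")
  cat("  argmax: productivity @", x$argmax$nadph_productivity,
      "% | availability @", x$argmax$nadph_availability,
      "% | MVA @", x$argmax$final_mva, "%\n")
  invisible(x)
}

#' Correlation between simulated and measured fluxes
#'
#' Pearson correlation over the reactions shared (case-insensitively) by a
#' simulated flux vector and a measured flux table.
#'
#' @param simulated named flux vector from [compute_fluxes()].
#' @param measured data.frame with columns \code{reaction} and \code{flux}
#'   (see [read_flux_table()]).
#' @return List with \code{r}, \code{p_value}, \code{n}, \code{matched}
#'   (reaction names used, for audit).
#' @export
flux_correlation <- function(simulated, measured) {
  stopifnot(is.data.frame(measured),
            all(c("reaction", "flux") %in% names(measured)))
  sim_names <- names(simulated)
  idx <- match(tolower(measured$reaction), tolower(sim_names))
  keep <- !is.na(idx)
  if (sum(keep) < 3L) {
    stop("fewer than 3 shared reactions between simulated and measured ",
         "fluxes", call. = FALSE)
  }
  x <- as.numeric(simulated[idx[keep]])
  y <- as.numeric(measured$flux[keep])
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep),
       matched = sim_names[idx[keep]])
}
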