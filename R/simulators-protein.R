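#' Benchmark simulator: mass-action protein network with destructive sampling
#'
#' A three-species protein interaction network with cycles, observed the way
#' mass cytometry observes it: at every sampling time a *different* cell is
#' measured and destroyed, so no cell yields a trajectory. Each sampled cell
#' has its own initial concentrations and rate constants (cell-to-cell
#' heterogeneity, lognormal jitter), and the instrument adds Gaussian
#' measurement noise. Experimental interventions inhibit a species by
#' clamping its activity to its resting baseline from `t = 0`.
#'
#' The underlying mass-action system over P1, P2, P3 and an *unmeasured*
#' complex C (a latent confounder) is
#' \deqn{\dot P_1 = -d_1 P_1 - k_b P_1 P_3}
#' \deqn{\dot P_2 = k_{21} P_1 - d_2 P_2}
#' \deqn{\dot P_3 = k_{32} P_2 - d_3 P_3}
#' \deqn{\dot C = k_b P_1 P_3 - k_{dC} C}
#' where P3 catalyzes the sequestration of P1 into the unmeasured complex
#' (P1 + P3 -> C + P3). The coarse signed graph over the measured species is
#' the cycle P1 -> P2 (+), P2 -> P3 (+), P3 -| P1 (-), the inhibition
#' mediated by the latent complex formation. With degradation switched off
#' (`d1 = kdC = 0`) the moiety `P1 + C` is conserved.
#'
#' @param experiments character vector of interventions to run, a subset of
#'   `c("none", "inhibit_P1", "inhibit_P2", "inhibit_P3", "combined")`
#'   (`"combined"` inhibits P2 and P3 together). Default: all five.
#' @param times sampling times (destructive: a fresh set of cells per time).
#' @param cells_per_time number of cells measured at each time point.
#' @param noise `"low"` or `"high"`; the high-uncertainty regime doubles the
#'   standard deviation of every stochastic term (measurement noise and
#'   heterogeneity).
#' @param measurement_sd additive Gaussian measurement noise sd (low regime).
#' @param heterogeneity lognormal sd of the per-cell jitter applied to
#'   initial concentrations and rate constants (low regime).
#' @param rates named list of rate constants; see [protein_rates()].
#' @param x0 initial (stimulated) concentrations of P1-P3.
#' @param baseline resting concentrations; inhibition clamps a species here.
#' @param seed RNG seed (required).
#' @return a list with `data` (long-format tibble: `experiment`, `time`,
#'   `variable`, `value`), `interventions` (tibble: `experiment`,
#'   `variable`, `type`), and `truth` (a `usdl_ground_truth` over the linear
#'   dictionary: coarse signed connectivity and edge list).
#' @export
simulate_protein_network <- function(
    experiments = c("none", "inhibit_P1", "inhibit_P2", "inhibit_P3", "combined"),
    times = 0:12,
    cells_per_time = 20L,
    noise = c("low", "high"),
    measurement_sd = 0.05,
    heterogeneity = 0.1,
    rates = protein_rates(),
    x0 = c(P1 = 5, P2 = 0.2, P3 = 0.2),
    baseline = c(P1 = 0.2, P2 = 0.2, P3 = 0.2),
    seed) {
  if (missing(seed)) abort("`seed` is required.")
  noise <- match.arg(noise)
  fac <- if (noise == "high") 2 else 1
  meas_sd <- fac * measurement_sd
  het <- fac * heterogeneity
  valid <- c("none", "inhibit_P1", "inhibit_P2", "inhibit_P3", "combined")
  bad <- setdiff(experiments, valid)
  if (length(bad)) abort(sprintf("invalid intervention target(s): %s",
                                 paste(bad, collapse = ", ")))
  vars <- c("P1", "P2", "P3")

  rows <- list()
  with_seed(seed, {
    for (ex in experiments) {
      clamped <- clamped_species(ex)
      for (ti in times) {
        # fresh cells for this (experiment, time): destructive sampling
        vals <- vapply(seq_len(cells_per_time), function(cell) {
          x0_cell <- x0 * exp(rnorm(3, sd = het))
          r_cell <- lapply(rates, function(r) r * exp(rnorm(1, sd = het)))
          tr <- protein_network_trajectory(c(0, ti), r_cell, x0_cell,
                                           baseline, clamped)
          tr[nrow(tr), vars]
        }, numeric(3))
        meas <- vals + rnorm(length(vals), sd = meas_sd)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          experiment = ex,
          time = ti,
          variable = rep(vars, times = cells_per_time),
          value = as.numeric(meas)
        )
      }
    }
  })
  data <- dplyr::bind_rows(rows)

  iv <- dplyr::bind_rows(lapply(experiments, function(ex) {
    cl <- clamped_species(ex)
    if (length(cl) == 0L) {
      tibble::tibble(experiment = ex, variable = NA_character_, type = "none")
    } else {
      tibble::tibble(experiment = ex, variable = cl, type = "inhibition")
    }
  }))

  A <- matrix(0, 3, 3, dimnames = list(vars, vars))
  A["P1", ] <- c(-rates$d1, 0, -rates$kb)
  A["P2", ] <- c(rates$k21, -rates$d2, 0)
  A["P3", ] <- c(0, rates$k32, -rates$d3)
  truth <- new_ground_truth(A, variables = vars, labels = vars,
                            config = list(system = "protein_network",
                                          experiments = experiments,
                                          times = times,
                                          cells_per_time = cells_per_time,
                                          noise = noise, rates = rates),
                            seed = seed)
  list(data = data, interventions = iv, truth = truth)
}

#' Default rate constants of the surrogate protein network
#'
#' Degradation `d1`-`d3`, catalytic production rates `k21` (P1 drives P2)
#' and `k32` (P2 drives P3), complex formation `kb` (P1 + P3 -> C) and
#' complex degradation `kdC`. Units: 1/time for first-order rates,
#' 1/(conc * time) for `kb`.
#'
#' @param d1,d2,d3,k21,k32,kb,kdC rate constants.
#' @return a named list.
#' @export
protein_rates <- function(d1 = 0.3, d2 = 0.8, d3 = 0.3,
                          k21 = 0.8, k32 = 0.5, kb = 0.15, kdC = 0.4) {
  list(d1 = d1, d2 = d2, d3 = d3, k21 = k21, k32 = k32, kb = kb, kdC = kdC)
}

clamped_species <- function(experiment) {
  switch(experiment,
         none = character(0),
         inhibit_P1 = "P1",
         inhibit_P2 = "P2",
         inhibit_P3 = "P3",
         combined = c("P2", "P3"),
         abort(sprintf("invalid intervention target '%s'", experiment)))
}

#' Deterministic trajectory of the surrogate protein network
#'
#' Integrates the mass-action system (including the latent complex C) with
#' an adaptive solver at tight tolerance. Clamped species are held at their
#' baseline for all times.
#'
#' @param times output times (must start at the initial time).
#' @param rates rate list, see [protein_rates()].
#' @param x0 initial concentrations of P1-P3 (clamped species are
#'   overridden by their baseline).
#' @param baseline resting concentrations.
#' @param clamped character vector of inhibited species.
#' @return matrix of concentrations (columns P1, P2, P3, C) at `times`.
#' @export
protein_network_trajectory <- function(times, rates = protein_rates(),
                                       x0 = c(P1 = 5, P2 = 0.2, P3 = 0.2),
                                       baseline = c(P1 = 0.2, P2 = 0.2, P3 = 0.2),
                                       clamped = character(0)) {
  y0 <- c(unname(x0), 0)
  names(y0) <- c("P1", "P2", "P3", "C")
  y0[clamped] <- baseline[clamped]
  clamp_idx <- match(clamped, names(y0))
  deriv <- function(t, y, parms) {
    vb <- parms$kb * y[1] * y[3]   # catalytic sequestration P1 + P3 -> C + P3
    dy <- c(-parms$d1 * y[1] - vb,
            parms$k21 * y[1] - parms$d2 * y[2],
            parms$k32 * y[2] - parms$d3 * y[3],
            vb - parms$kdC * y[4])
    if (length(clamp_idx)) dy[clamp_idx] <- 0
    list(dy)
  }
  if (length(times) == 1L || max(times) == min(times)) {
    out <- matrix(rep(y0, each = length(times)), length(times), 4)
  } else {
    sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = rates,
                        rtol = 1e-8, atol = 1e-10)
    out <- unname(sol[, -1, drop = FALSE])
  }
  colnames(out) <- c("P1", "P2", "P3", "C")
  out
}
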