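#' Membrane parameters for the five-conductance RGC model
#'
#' Channel densities and cable constants of a Fohlmeister-Miller-type
#' retinal ganglion cell: fast sodium, calcium, delayed-rectifier potassium,
#' A-type potassium, and calcium-activated potassium conductances plus leak,
#' with internal calcium dynamics setting the Ca reversal through the Nernst
#' relation.  Densities vary by section; the sodium band (axon initial
#' segment) carries a high sodium density, which is where spikes initiate
#' under extracellular stimulation.  The leak reversal of every section is
#' solved at initialisation so that `v_rest_mv` is an exact equilibrium of
#' the full system (see [resting_state()]).
#'
#' @param densities data.frame with one row per section (`section`, `gna`,
#'   `gca`, `gk`, `ga`, `gkca`, in mS/cm^2).
#' @param gl_mS_cm2 leak conductance density.
#' @param cm_uF_cm2 specific membrane capacitance.
#' @param ri_ohm_cm axial (cytoplasmic) resistivity.
#' @param ena_mv,ek_mv sodium / potassium reversal potentials (mV).
#' @param cao_mM external calcium (mM).
#' @param cares_mM residual internal calcium (mM).
#' @param tau_ca_ms internal calcium removal time constant (ms).
#' @param cadiss_mM calcium dissociation constant of the KCa conductance.
#' @param v_rest_mv target resting potential (mV).
#' @param temperature_K temperature used for the Ca Nernst factor.
#' @return list of class `membrane_params`.
#' @export
rgc_membrane_params <- function(
    densities = data.frame(
      section = c("dendrite", "soma", "hillock", "sodium_band", "axon"),
      gna  = c(40, 80, 150, 700, 100),
      gca  = c(2.0, 1.5, 1.5, 1.5, 0),
      gk   = c(12, 18, 18, 18, 18),
      ga   = c(36, 54, 54, 54, 0),
      gkca = c(0.05, 0.065, 0.065, 0.065, 0),
      stringsAsFactors = FALSE),
    gl_mS_cm2 = 0.05, cm_uF_cm2 = 1, ri_ohm_cm = 110,
    ena_mv = 35, ek_mv = -75, cao_mM = 1.8, cares_mM = 1e-4,
    tau_ca_ms = 1.5, cadiss_mM = 1e-3, v_rest_mv = -65,
    temperature_K = 295.15) {
  stopifnot(all(c("section", "gna", "gca", "gk", "ga", "gkca") %in%
                  names(densities)),
            all(densities[, -1] >= 0), gl_mS_cm2 > 0)
  structure(as.list(environment()), class = "membrane_params")
}

## Steady-state gating values at voltage v (mV); mirrors the C++ kinetics.
fm_gates_inf <- function(v) {
  expdec <- function(u) ifelse(abs(u) < 1e-6, 1 - u / 2, u / (exp(u) - 1))
  am <- 6 * expdec(-0.1 * (v + 30)); bm <- 20 * exp(-(v + 55) / 18)
  ah <- 0.4 * exp(-(v + 50) / 20);   bh <- 6 / (1 + exp(-0.1 * (v + 20)))
  ac <- 3 * expdec(-0.1 * (v + 13)); bc <- 10 * exp(-(v + 38) / 18)
  an <- 0.2 * expdec(-0.1 * (v + 40)); bn <- 0.4 * exp(-(v + 50) / 80)
  aa <- 0.06 * expdec(-0.1 * (v + 90)); ba <- 0.1 * exp(-(v + 30) / 10)
  aha <- 0.04 * exp(-(v + 70) / 20); bha <- 0.6 / (1 + exp(-0.1 * (v + 40)))
  list(m = am / (am + bm), h = ah / (ah + bh), c = ac / (ac + bc),
       n = an / (an + bn), a = aa / (aa + ba), ha = aha / (aha + bha))
}

#' Assemble the numerical cable model of a neuron
#'
#' Converts a [build_neuron()] compartment table and [rgc_membrane_params()]
#' into the absolute-quantity arrays used by the time stepper: per-compartment
#' membrane conductances (mS), capacitances (uF), calcium source factors,
#' per-section leak reversals solved so the resting potential is an exact
#' equilibrium, and axial conductances (mS) along the compartment chain.
#'
#' @param neuron a [build_neuron()] data.frame.
#' @param mem a [rgc_membrane_params()].
#' @return list of class `cable_model` consumed by [simulate_rgc()].
#' @export
cable_model <- function(neuron, mem = rgc_membrane_params()) {
  sec <- match(neuron$section, mem$densities$section)
  if (anyNA(sec))
    stop("membrane densities missing for section(s): ",
         paste(unique(neuron$section[is.na(sec)]), collapse = ", "))
  d_cm <- neuron$diameter_um * 1e-4
  L_cm <- neuron$length_um * 1e-4
  area <- ifelse(neuron$section == "soma", pi * d_cm^2, pi * d_cm * L_cm)

  dens <- mem$densities[sec, ]
  rtf2 <- 1000 * 8.314 * mem$temperature_K / (2 * 96485)

  ## per-section leak reversal: solve the rest equilibrium, including the
  ## self-consistent resting calcium level of Ca-bearing sections
  v0 <- mem$v_rest_mv
  g0 <- fm_gates_inf(v0)
  el_of_section <- function(gna, gca, gk, ga, gkca, d_um) {
    ca <- mem$cares_mM
    r_cm <- d_um / 2 * 1e-4
    caf_dens <- 3e-3 / (2 * 96485 * r_cm)      # per (uA/cm^2)
    for (i in 1:25) {
      eca <- rtf2 * log(mem$cao_mM / ca)
      ica <- gca * g0$c^3 * (v0 - eca)
      ca <- mem$cares_mM - mem$tau_ca_ms * caf_dens * ica
      ca <- max(ca, 1e-8)
    }
    eca <- rtf2 * log(mem$cao_mM / ca)
    gkca_eff <- gkca * (ca / mem$cadiss_mM)^2 / (1 + (ca / mem$cadiss_mM)^2)
    iion <- gna * g0$m^3 * g0$h * (v0 - mem$ena_mv) +
      gca * g0$c^3 * (v0 - eca) +
      (gk * g0$n^4 + ga * g0$a^3 * g0$ha + gkca_eff) * (v0 - mem$ek_mv)
    list(el = v0 + iion / mem$gl_mS_cm2, ca = ca)
  }
  el <- numeric(nrow(neuron)); ca0 <- numeric(nrow(neuron))
  for (i in seq_len(nrow(neuron))) {
    sol <- el_of_section(dens$gna[i], dens$gca[i], dens$gk[i], dens$ga[i],
                         dens$gkca[i], neuron$diameter_um[i])
    el[i] <- sol$el; ca0[i] <- sol$ca
  }

  ## axial conductances between consecutive compartments (mS)
  a_cross <- pi * d_cm^2 / 4
  r_half <- mem$ri_ohm_cm * (L_cm / 2) / a_cross    # ohm
  n <- nrow(neuron)
  gax <- 1000 / (r_half[-n] + r_half[-1])

  r_cm <- d_cm / 2
  caf <- ifelse(dens$gca > 0, 3e-3 / (2 * 96485 * r_cm * area), 0)

  structure(list(
    gna = dens$gna * area, gca = dens$gca * area, gk = dens$gk * area,
    ga = dens$ga * area, gkca = dens$gkca * area,
    gl = rep(mem$gl_mS_cm2, n) * area, el = el,
    cm = rep(mem$cm_uF_cm2, n) * area, gax = gax, caf = caf,
    ena = mem$ena_mv, ek = mem$ek_mv, cao = mem$cao_mM,
    cares = mem$cares_mM, tau_ca = mem$tau_ca_ms, cadiss = mem$cadiss_mM,
    rtf2 = rtf2, v_rest = v0, ca0 = ca0,
    n_comp = n, section = neuron$section, area_cm2 = area
  ), class = "cable_model")
}

#' Resting state of a cable model
#'
#' @param model a [cable_model()].
#' @return list of state vectors (`v`, gating variables, `ca`) at the
#'   configured resting potential.
#' @export
resting_state <- function(model) {
  v <- rep(model$v_rest, model$n_comp)
  g <- fm_gates_inf(model$v_rest)
  list(v = v,
       m = rep(g$m, model$n_comp), h = rep(g$h, model$n_comp),
       c = rep(g$c, model$n_comp), n = rep(g$n, model$n_comp),
       a = rep(g$a, model$n_comp), ha = rep(g$ha, model$n_comp),
       ca = model$ca0)
}
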