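#' Convert a log10 affinity to an equilibrium dissociation constant
#'
#' Affinities of high-affinity fluorescent antagonists are conventionally
#' reported as log10(1/M); the corresponding Kd is `10^(-log_affinity)` molar.
#'
#' @param log_affinity log10 of the association constant (log10(1/M)).
#' @return Kd in molar.
#' @examples
#' log_affinity_to_kd(10.35)  # ~4.5e-11 M (~45 pM)
#' @export
log_affinity_to_kd <- function(log_affinity) {
  stop_if_not_scalar_number(log_affinity, "log_affinity")
  10^(-log_affinity)
}

#' Equilibrium fractional occupancy of a 1:1 binding site
#'
#' Simple mass-action occupancy `L / (L + Kd)` for a ligand binding a single
#' site with 1:1 stoichiometry, assuming negligible ligand depletion
#' (free concentration equal to total).
#'
#' @param ligand_conc free ligand concentration, molar. May be a vector.
#' @param kd equilibrium dissociation constant, molar (> 0).
#' @return occupied fraction in \[0, 1\], same length as `ligand_conc`.
#' @examples
#' fractional_occupancy(10e-9, log_affinity_to_kd(10.35))  # > 0.995
#' @export
fractional_occupancy <- function(ligand_conc, kd) {
  stop_if_not_scalar_number(kd, "kd", min = 0, allow_zero = FALSE)
  if (any(!is.finite(ligand_conc)) || any(ligand_conc < 0))
    stop("'ligand_conc' must be finite and >= 0", call. = FALSE)
  ligand_conc / (ligand_conc + kd)
}

#' Single-site competition binding curve
#'
#' Fraction of sites occupied by a fixed concentration of tracer ligand in
#' the presence of an unlabeled competitor, under the standard single-site
#' competitive model (Hill slope 1, no cooperativity):
#' `bound = (L/Kd) / (1 + L/Kd + I/Ki)`.
#' The half-inhibition point obeys the Cheng-Prusoff relation
#' `IC50 = Ki * (1 + L/Kd)`.
#'
#' @param tracer_conc tracer concentration L, molar.
#' @param tracer_kd tracer Kd, molar (> 0).
#' @param competitor_concs vector of competitor concentrations I, molar.
#' @param competitor_ki competitor Ki, molar (> 0).
#' @return data.frame with columns `competitor_conc` and `bound_fraction`.
#' @examples
#' competition_curve(1e-9, 45e-12, c(0, 1e-9, 1e-8, 1e-7), 1e-9)
#' @export
competition_curve <- function(tracer_conc, tracer_kd, competitor_concs,
                              competitor_ki) {
  stop_if_not_scalar_number(tracer_conc, "tracer_conc", min = 0)
  stop_if_not_scalar_number(tracer_kd, "tracer_kd", min = 0, allow_zero = FALSE)
  stop_if_not_scalar_number(competitor_ki, "competitor_ki", min = 0,
                            allow_zero = FALSE)
  if (length(competitor_concs) == 0L)
    return(data.frame(competitor_conc = numeric(0),
                      bound_fraction = numeric(0)))
  if (any(!is.finite(competitor_concs)) || any(competitor_concs < 0))
    stop("competitor concentrations must be finite and >= 0", call. = FALSE)
  lr <- tracer_conc / tracer_kd
  bound <- lr / (1 + lr + competitor_concs / competitor_ki)
  data.frame(competitor_conc = competitor_concs, bound_fraction = bound)
}

#' Cheng-Prusoff half-inhibition concentration
#'
#' @param tracer_conc tracer concentration, molar.
#' @param tracer_kd tracer Kd, molar.
#' @param competitor_ki competitor Ki, molar.
#' @return IC50 in molar.
#' @export
cheng_prusoff_ic50 <- function(tracer_conc, tracer_kd, competitor_ki) {
  competitor_ki * (1 + tracer_conc / tracer_kd)
}
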