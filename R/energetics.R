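#' Mean interaction energy of a sampled series
#'
#' Arithmetic mean of a per-frame interaction-energy series (kcal/mol).
#' The mean is invariant to frame ordering; frames are assumed equally
#' spaced so no weighting is applied.
#'
#' @param values numeric vector of per-frame energies (kcal/mol).
#' @return scalar mean energy (kcal/mol).
#' @examples
#' average_energy(c(-1, -2, -3))  # -2
#' @export
average_energy <- function(values) {
  if (length(values) == 0L)
    stop("energy series is empty", call. = FALSE)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("energy series must be finite numeric", call. = FALSE)
  mean(values)
}

#' Averaged interaction-energy components for end-point estimators
#'
#' Bundle of the mean ligand--surroundings interaction energies entering the
#' LIE and LRA estimators: van der Waals and electrostatic means in the
#' bound (protein, P) and free (water, W) states, plus the optional
#' preorganized electrostatic term sampled with all ligand partial charges
#' set to zero.
#'
#' @param vdw_bound mean ligand-protein van der Waals energy (kcal/mol).
#' @param vdw_free mean ligand-water van der Waals energy (kcal/mol).
#' @param ele_bound mean ligand-protein electrostatic energy (kcal/mol).
#' @param ele_free mean ligand-water electrostatic energy (kcal/mol).
#' @param ele_bound_uncharged mean ligand-protein electrostatic energy with
#'   ligand charges zeroed (kcal/mol); required for LRA, may be `NA` for LIE.
#' @return an object of class `"energy_components"`.
#' @export
energy_components <- function(vdw_bound, vdw_free, ele_bound, ele_free,
                              ele_bound_uncharged = NA_real_) {
  core <- c(vdw_bound = vdw_bound, vdw_free = vdw_free,
            ele_bound = ele_bound, ele_free = ele_free)
  if (!all(is.finite(core)))
    stop("all four charged-state components must be finite", call. = FALSE)
  if (!is.na(ele_bound_uncharged) && !is.finite(ele_bound_uncharged))
    stop("ele_bound_uncharged must be finite or NA", call. = FALSE)
  structure(list(vdw_bound = as.numeric(vdw_bound),
                 vdw_free = as.numeric(vdw_free),
                 ele_bound = as.numeric(ele_bound),
                 ele_free = as.numeric(ele_free),
                 ele_bound_uncharged = as.numeric(ele_bound_uncharged)),
            class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat("Averaged interaction-energy components (kcal/mol)\n")
  cat(sprintf("  vdW   bound %8.2f   free %8.2f\n", x$vdw_bound, x$vdw_free))
  cat(sprintf("  ele   bound %8.2f   free %8.2f\n", x$ele_bound, x$ele_free))
  if (!is.na(x$ele_bound_uncharged))
    cat(sprintf("  ele   bound, ligand uncharged %8.2f\n",
                x$ele_bound_uncharged))
  invisible(x)
}

#' LIE scaling coefficients
#'
#' The dimensionless coefficients of the linear-interaction-energy
#' estimator. Defaults alpha = 0.5, beta = 1.043 (the refined beta of
#' Paulsen & Ornstein, appropriate for buried polar binding sites); the
#' original Aqvist value beta = 0.16 can be selected explicitly but is
#' never applied silently.
#'
#' @param alpha van der Waals scaling, > 0.
#' @param beta electrostatic scaling, > 0.
#' @return object of class `"lie_coefficients"`.
#' @export
lie_coefficients <- function(alpha = 0.5, beta = 1.043) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "lie_coefficients")
}

new_binding_free_energy <- function(method, dG, sd = NA_real_,
                                    n_replicates = 1L) {
  structure(list(method = method, dG = dG, sd = sd,
                 n_replicates = as.integer(n_replicates)),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, digits = 2, ...) {
  lab <- c(LIE = "LIE", LRA = "LRA", experimental = "experimental (RT ln Ki)")
  cat(sprintf("Binding free energy [%s]: %.*f", lab[[x$method]], digits, x$dG))
  if (!is.na(x$sd))
    cat(sprintf(" +/- %.*f (n = %d)", digits, x$sd, x$n_replicates))
  cat(" kcal/mol\n")
  invisible(x)
}

#' Linear interaction energy (LIE) binding free energy
#'
#' dG = alpha * (<VvdW>_bound - <VvdW>_free) + beta * (<Vele>_bound -
#' <Vele>_free), all terms averaged over the simulation with regular
#' ligand charges.
#'
#' @param components an [energy_components()] object.
#' @param coefficients a [lie_coefficients()] object.
#' @return object of class `"binding_free_energy"` with `method = "LIE"`.
#' @examples
#' cmp <- energy_components(-40.52, -23.49, -36.05, -36.7)
#' lie_free_energy(cmp)   # about -7.84 kcal/mol
#' @export
lie_free_energy <- function(components, coefficients = lie_coefficients()) {
  stopifnot(inherits(components, "energy_components"),
            inherits(coefficients, "lie_coefficients"))
  dG <- coefficients$alpha * (components$vdw_bound - components$vdw_free) +
    coefficients$beta * (components$ele_bound - components$ele_free)
  new_binding_free_energy("LIE", dG)
}

#' Linear response approximation (LRA) binding free energy
#'
#' The LIE estimate plus the preorganized-electrostatics term
#' beta * <Vele>_0, the ligand-protein electrostatic energy sampled with
#' ligand charges zeroed. A negative term indicates binding-site dipoles
#' pre-oriented toward the uncharged ligand.
#'
#' @inheritParams lie_free_energy
#' @return object of class `"binding_free_energy"` with `method = "LRA"`.
#' @export
lra_free_energy <- function(components, coefficients = lie_coefficients()) {
  stopifnot(inherits(components, "energy_components"),
            inherits(coefficients, "lie_coefficients"))
  if (is.na(components$ele_bound_uncharged))
    stop("LRA requires the uncharged-ligand electrostatic component",
         call. = FALSE)
  lie <- lie_free_energy(components, coefficients)
  dG <- lie$dG + coefficients$beta * components$ele_bound_uncharged
  new_binding_free_energy("LRA", dG)
}

#' Aggregate per-replicate binding free energies
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' per-replicate estimates, the convention for independent production runs.
#'
#' @param estimates list of `"binding_free_energy"` objects, all computed by
#'   the same method, length >= 2.
#' @return a `"binding_free_energy"` with `sd` and `n_replicates` filled in.
#' @export
aggregate_replicates <- function(estimates) {
  if (!is.list(estimates) ||
      !all(vapply(estimates, inherits, TRUE, "binding_free_energy")))
    stop("estimates must be a list of binding_free_energy objects",
         call. = FALSE)
  if (length(estimates) < 2L)
    stop("replicate aggregation needs at least 2 replicates", call. = FALSE)
  methods <- vapply(estimates, `[[`, "", "method")
  if (length(unique(methods)) != 1L)
    stop("cannot aggregate estimates from different methods", call. = FALSE)
  vals <- vapply(estimates, `[[`, 0, "dG")
  new_binding_free_energy(methods[[1L]], mean(vals), sd(vals),
                          length(vals))
}

#' Thermodynamic constants for converting Ki to a free energy
#'
#' @param temperature absolute temperature in K (default 310.15 K, the
#'   value that reproduces the study's tabulated experimental free
#'   energies; the assay temperature 298.15 K is equally valid input).
#' @param gas_constant in kcal mol^-1 K^-1.
#' @param c_ref reference concentration in M (1 M standard state).
#' @return object of class `"thermo_constants"`.
#' @export
thermo_constants <- function(temperature = 310.15,
                             gas_constant = 1.9872e-3, c_ref = 1) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0", call. = FALSE)
  if (!is.finite(gas_constant) || gas_constant <= 0)
    stop("gas_constant must be > 0", call. = FALSE)
  if (!is.finite(c_ref) || c_ref <= 0)
    stop("c_ref must be > 0", call. = FALSE)
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 c_ref = c_ref), class = "thermo_constants")
}

#' Experimental binding free energy from an inhibition constant
#'
#' dG = R T ln(Ki / c_ref). Strictly increasing in Ki; Ki at the 1 M
#' reference state gives 0.
#'
#' @param ki inhibition constant in molar units, > 0.
#' @param thermo a [thermo_constants()] object.
#' @return object of class `"binding_free_energy"`, `method = "experimental"`.
#' @examples
#' ki_to_free_energy(3.67e-6)  # about -7.71 kcal/mol at 310.15 K
#' @export
ki_to_free_energy <- function(ki, thermo = thermo_constants()) {
  stopifnot(inherits(thermo, "thermo_constants"))
  if (!is.finite(ki) || ki <= 0)
    stop("Ki must be a positive molar concentration", call. = FALSE)
  dG <- thermo$gas_constant * thermo$temperature * log(ki / thermo$c_ref)
  new_binding_free_energy("experimental", dG)
}

#' Binding free energy from a long-format energy table
#'
#' Full pipeline from per-frame sampled energies to a replicate-aggregated
#' estimate: for each replicate, average the vdW and electrostatic series in
#' the bound and free states (and the uncharged-ligand bound state for LRA),
#' apply the estimator, then aggregate across replicates.
#'
#' @param energies data frame in the energy-table dialect (columns `frame`,
#'   `replicate`, `state` in `bound|free|bound_q0`, `vdw`, `ele`); see
#'   [read_energy_table()].
#' @param method `"LIE"` or `"LRA"`.
#' @param coefficients a [lie_coefficients()] object.
#' @return `"binding_free_energy"`; aggregated when >= 2 replicates are
#'   present, otherwise the single-replicate estimate.
#' @export
binding_energy_from_table <- function(energies, method = c("LIE", "LRA"),
                                      coefficients = lie_coefficients()) {
  method <- match.arg(method)
  validate_energy_table(energies)
  per_rep <- lapply(split(energies, energies$replicate), function(df) {
    comp_of <- function(state, col) {
      v <- df[[col]][df$state == state]
      if (length(v) == 0L)
        stop(sprintf("replicate %s has no '%s' rows", df$replicate[[1L]],
                     state), call. = FALSE)
      average_energy(v)
    }
    q0 <- if (any(df$state == "bound_q0"))
      comp_of("bound_q0", "ele") else NA_real_
    cmp <- energy_components(comp_of("bound", "vdw"), comp_of("free", "vdw"),
                             comp_of("bound", "ele"), comp_of("free", "ele"),
                             ele_bound_uncharged = q0)
    if (method == "LIE") lie_free_energy(cmp, coefficients)
    else lra_free_energy(cmp, coefficients)
  })
  if (length(per_rep) >= 2L) aggregate_replicates(unname(per_rep))
  else per_rep[[1L]]
}
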