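#' @title Model parameter registry
#'
#' @description
#' All kinetic, transport, boundary and mechanical constants of the AAA
#' model, in the canonical (g, cm, day) unit system; mechanical moduli and
#' pressures are carried in N/cm^2 (the mechanics subsystem is closed in
#' N and cm, and couples to the biology only through dimensionless ratios
#' S/S0 and rho/rho*). A handful of constants absent from the published
#' tables are closed by steady-state consistency or set to documented
#' defaults and flagged with provenance `"assumed"`.
#'
#' @name aaa_params
NULL

# Default constants. Units: diffusion cm^2/day; first-order rates day^-1;
# binding rates cm^3 g^-1 day^-1; saturations/concentrations g cm^-3;
# chemotaxis cm^5 g^-1 day^-1; exchange rates (alpha_*, gamma_*) act as
# exchange velocities in the weak form (see robin_coefficients);
# moduli/pressures N cm^-2; blood pressure in mmHg (converted on load).
.aaa_defaults <- function() {
  list(
    # diffusion
    D_P = 1.728e-1, D_M = 8.64e-7, D_T = 8.64e-7, D_S = 8.64e-7,
    D_I6 = 1.08e-2, D_I10 = 1.08e-2, D_I12 = 1.08e-2,
    D_Ta = 1.29e-2, D_Ig = 1.08e-2, D_Q = 4.32e-2, D_Qr = 4.32e-2,
    D_r = 8.64e-7,                       # assumed: ECM quasi-immobile
    # production / activation
    lambda_PS = 3e-3, lambda_MIg = 5e-3, lambda_MTa = 1,  # lambda_MTa assumed
    lambda_T = 6e-4, lambda_S = NA_real_,                 # closed on load
    lambda_I6M = 1.73e-6, lambda_I6S = 1.73e-5,
    lambda_I10M = 2e-3, lambda_I12M = 3.78e-3, lambda_TaM = 2.86e-3,
    lambda_IgT = 2.34e-6,
    lambda_QM = 3e-4, lambda_QS = 2.16e-5, lambda_QTa = 2, lambda_QrM = 6e-5,
    lambda_rf = 3e-4, lambda_rS = 1e-1,
    # degradation / death / apoptosis
    d_P = 1.73, d_PM = 2.08e-4, d_M = 0.015, d_T = 0.197,  # d_T assumed
    d_S = 0.86, d_SM = 1.72, d_I6 = 0.173, d_I10 = 16.64,
    d_I12 = 1.188, d_Ta = 55.45, d_Ig = 0.69,
    d_Q = 4.32, d_Qr = 21.6, d_r = 0.37,
    # binding
    d_QQr = 4.98e8, d_QrQ = 1.04e9, d_rQ = 2.59e7,
    # saturations
    K_M = 5e-5, K_P = 5e-9, K_Ig = 1e-11, K_I10 = 2e-7, K_Ta = 5e-7,
    # carrying capacity and boundary sources
    rho0 = 1e-3, M0 = 5e-5, T0 = 1e-3, P0 = 3e-10, S0 = 6e-3, I60 = 6e-9,
    # influx / exchange rates; text values for the interface
    # (the tabled single interface rate 0.1 is superseded by the
    # species-class-specific values 50 for cells, 500 for cytokines)
    alpha_M = 0.2, alpha_T = 0.2, alpha_P = 0.2, alpha_I6 = 0.2,
    gamma_cell = 50, gamma_cytokine = 500,
    # chemotaxis
    chi_C = 10,
    # mechanics
    beta10 = 17.4, beta20 = 188.1, k1 = 30.4, k2 = 84,
    beta_p = 18, p_star = 37, rho_star = 3.43e-4,
    p_B_mmHg = 110, gamma_surf = 1e-2,
    # initial tissue state
    Q_init = 3e-8, Qr_init = 1e-8, rho_init = 3.43e-4,
    # mechanics discretisation switches
    piola_variant = "energy",      # "energy" (Eq-15 coefficient) or "paper"
    adventitia_smc = NA_real_      # SMC density used for moduli in the
                                   # adventitia; NA -> S0 (no SMC loss there)
  )
}

.assumed_keys <- c("D_r", "lambda_MTa", "d_T", "gamma_surf", "adventitia_smc")

#' Load the model parameter set
#'
#' Builds the full parameter registry, applying overrides from a named list
#' or a YAML file. Unknown keys and negative rates are rejected. The SMC
#' source `lambda_S` is closed by steady-state consistency
#' (`lambda_S = d_S * S0`, see [close_smc_source()]) unless overridden.
#' Blood pressure is converted from mmHg to N/cm^2 on load (`p_B`).
#'
#' @param config `NULL`, a named list of overrides, or the path to a YAML
#'   file with a flat key-value mapping.
#' @return an object of class `aaa_params`: a named list of constants with a
#'   `provenance` attribute (`"default"`, `"override"`, `"assumed"` or
#'   `"derived"` per key).
#' @examples
#' p <- load_parameters()
#' p$D_M                       # 8.64e-7 cm^2/day
#' p2 <- load_parameters(list(I60 = 6e-8))
#' @export
load_parameters <- function(config = NULL) {
  defaults <- .aaa_defaults()
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (length(config) && (is.null(names(config)) || any(names(config) == ""))) {
    stop("config overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- defaults
  prov <- stats::setNames(rep("default", length(p)), names(p))
  prov[.assumed_keys] <- "assumed"
  for (k in names(config)) {
    p[[k]] <- config[[k]]
    prov[[k]] <- "override"
  }
  # sign guards on all numeric scalars (rates, concentrations, moduli)
  num <- names(p)[vapply(p, function(x) is.numeric(x) && length(x) == 1, TRUE)]
  for (k in setdiff(num, c("lambda_S", "adventitia_smc"))) {
    if (!is.na(p[[k]]) && p[[k]] < 0) {
      stop("parameter ", k, " must be nonnegative (got ", p[[k]], ")",
           call. = FALSE)
    }
  }
  if (is.na(p$lambda_S)) {
    p$lambda_S <- close_smc_source(p$d_S, p$S0)
    prov[["lambda_S"]] <- "derived"
  } else if (p$lambda_S < 0) {
    stop("parameter lambda_S must be nonnegative", call. = FALSE)
  }
  if (is.na(p$adventitia_smc)) p$adventitia_smc <- p$S0
  p$p_B <- convert_pressure(p$p_B_mmHg, "mmHg", "N/cm^2")
  prov[["p_B"]] <- "derived"
  # moduli must be positive at the disease calibration point S = S0/2
  em <- c(p$beta10 - p$k1 / 2, p$beta20 - p$k2 / 2)
  if (any(em <= 0)) {
    stop("elastic moduli non-positive at S = S0/2: beta1 = ", em[1],
         ", beta2 = ", em[2], " N/cm^2", call. = FALSE)
  }
  structure(p, provenance = prov, class = "aaa_params")
}

#' @export
print.aaa_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<aaa_params> ", length(x), " constants (",
      sum(prov == "override"), " overridden, ",
      sum(prov == "assumed"), " assumed)\n", sep = "")
  invisible(x)
}

#' Machine-readable parameter dump
#'
#' @param params an `aaa_params` object.
#' @param path optional path; if given, a JSON dump (key, value, provenance)
#'   is written there.
#' @return invisibly, a data frame with columns `key`, `value`, `provenance`.
#' @export
dump_parameters <- function(params, path = NULL) {
  prov <- attr(params, "provenance")
  num <- vapply(params, function(x) is.numeric(x) && length(x) == 1, TRUE)
  df <- data.frame(
    key = names(params)[num],
    value = unlist(params[num], use.names = FALSE),
    provenance = unname(prov[names(params)[num]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}

#' Derive IL-6 production rates from steady-state secretion assays
#'
#' Production rates of IL-6 by macrophages and by smooth muscle cells are
#' obtained from the steady-state balance `lambda * X - d_I6 * I6 = 0` of
#' the IL-6 equation applied to in-vitro secretion assays (a known cell
#' density producing a known IL-6 level). The caller supplies densities in
#' g/cm^3 (cell counts converted at 1e6 cells/ml = 1e-3 g/cm^3).
#'
#' @param assay_M,assay_S numeric length-2 vectors `c(cell_density,
#'   il6_level)` in g/cm^3 for the macrophage and SMC assays.
#' @param d_I6 IL-6 degradation rate (day^-1).
#' @return named numeric vector `c(lambda_I6M =, lambda_I6S =)` in day^-1.
#' @examples
#' derive_il6_production_rates(c(1e-3, 1e-8), c(4e-5, 4e-9), 0.173)
#' @export
derive_il6_production_rates <- function(assay_M, assay_S, d_I6 = 0.173) {
  one <- function(a, label) {
    if (a[1] <= 0) stop("zero cell density in assay ", label, call. = FALSE)
    d_I6 * a[2] / a[1]
  }
  c(lambda_I6M = one(assay_M, "M"), lambda_I6S = one(assay_S, "S"))
}

#' Derive the moduli degradation slopes k1, k2
#'
#' The moduli law `beta = beta_healthy + k * (S/S0 - 1)` is calibrated from
#' the measured healthy and diseased moduli assuming the diseased wall has
#' SMC density `S_fraction * S0` (the calibration uses S about half normal).
#' Inputs are in N/mm^2 as reported in the tissue-testing literature; the
#' result is converted to N/cm^2.
#'
#' @param beta_dis diseased-tissue modulus (N/mm^2).
#' @param beta_healthy healthy-tissue modulus (N/mm^2).
#' @param S_fraction SMC fraction S/S0 in the diseased tissue, in (0, 1).
#' @return slope k in N/cm^2.
#' @examples
#' derive_elastic_coefficients(0.022, 0.174, 0.5)  # 30.4
#' derive_elastic_coefficients(1.461, 1.881, 0.5)  # 84
#' @export
derive_elastic_coefficients <- function(beta_dis, beta_healthy, S_fraction) {
  if (S_fraction <= 0 || S_fraction >= 1) {
    stop("S_fraction must be in (0, 1)", call. = FALSE)
  }
  k_nmm2 <- (beta_dis - beta_healthy) / (S_fraction - 1)
  convert_pressure(k_nmm2, "N/mm^2", "N/cm^2")
}

#' Derive the ECM pressure-law parameters p*, beta_p
#'
#' The affine tissue-pressure law `p(rho) = p* - beta_p (1 - rho/rho*)` is
#' calibrated from measured peak wall stress ranges: `p*` is the midpoint of
#' the healthy range, and `beta_p` solves `p(ecm_fraction * rho*) =` the
#' midpoint of the AAA range, assuming ECM in AAA is reduced to
#' `ecm_fraction` of healthy.
#'
#' @param stress_range_healthy,stress_range_AAA length-2 `c(lo, hi)` in N/cm^2.
#' @param ecm_fraction rho/rho* in AAA tissue, in (0, 1).
#' @return named numeric vector `c(p_star =, beta_p =)` in N/cm^2.
#' @examples
#' derive_pressure_params(c(30, 44), c(28, 37), 0.75)  # p* = 37, beta_p = 18
#' @export
derive_pressure_params <- function(stress_range_healthy, stress_range_AAA,
                                   ecm_fraction = 0.75) {
  if (ecm_fraction <= 0 || ecm_fraction >= 1) {
    stop("ecm_fraction must be in (0, 1)", call. = FALSE)
  }
  p_star <- mean(stress_range_healthy)
  p_aaa <- mean(stress_range_AAA)
  beta_p <- (p_star - p_aaa) / (1 - ecm_fraction)
  c(p_star = p_star, beta_p = beta_p)
}

#' Close the SMC source by steady-state consistency
#'
#' The SMC source term `lambda_S` is not tabulated; it is fixed so that the
#' healthy, macrophage-free tissue is stationary at the reported baseline
#' density S0: with no macrophages the SMC balance reads
#' `lambda_S - d_S * S = 0`, hence `lambda_S = d_S * S0`.
#'
#' @param d_S SMC death rate (day^-1).
#' @param S0 baseline SMC density (g/cm^3).
#' @return lambda_S in g cm^-3 day^-1.
#' @examples
#' close_smc_source(0.86, 6e-3)  # 5.16e-3
#' @export
close_smc_source <- function(d_S, S0) {
  d_S * S0
}

#' Reproduce the literature-to-parameter derivations
#'
#' Recomputes every derived constant from its printed literature inputs
#' (secretion assays, tissue moduli, peak-wall-stress ranges) and prints a
#' small table against the registry defaults.
#'
#' @param quiet if `TRUE`, do not print.
#' @return invisibly, a named numeric vector of the derived values:
#'   `lambda_I6M`, `lambda_I6S` (day^-1), `k1`, `k2`, `beta_p`, `p_star`
#'   (N/cm^2), `lambda_S` (g cm^-3 day^-1).
#' @export
check_params <- function(quiet = FALSE) {
  # assays: 1e6 macrophages/ml produced 10 ng/ml IL-6; 4e4 SMC/ml produced
  # 4 ng/ml; cell-count-to-mass convention 1e6 cells/ml = 1e-3 g/cm^3
  il6 <- derive_il6_production_rates(
    assay_M = c(1e6 / 1e6 * 1e-3, 10e-9),
    assay_S = c(4e4 / 1e6 * 1e-3, 4e-9),
    d_I6 = 0.173
  )
  k1 <- derive_elastic_coefficients(0.022, 0.174, 0.5)
  k2 <- derive_elastic_coefficients(1.461, 1.881, 0.5)
  pp <- derive_pressure_params(c(30, 44), c(28, 37), 0.75)
  lam_S <- close_smc_source(0.86, 6e-3)
  out <- c(il6, k1 = k1, k2 = k2, beta_p = unname(pp["beta_p"]),
           p_star = unname(pp["p_star"]), lambda_S = lam_S)
  if (!quiet) {
    defaults <- .aaa_defaults()
    ref <- c(defaults$lambda_I6M, defaults$lambda_I6S, defaults$k1,
             defaults$k2, defaults$beta_p, defaults$p_star,
             defaults$d_S * defaults$S0)
    df <- data.frame(parameter = names(out), derived = unname(out),
                     registry = ref)
    print(df, row.names = FALSE)
  }
  invisible(out)
}
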