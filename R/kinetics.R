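#' Species identifiers
#'
#' Stable string ids for the twelve model species, in canonical order:
#' MCP-1, macrophages, T cells, smooth muscle cells, IL-6, IL-10, IL-12,
#' TNF-alpha, IFN-gamma, MMP, TIMP, ECM. These names are used for state
#' matrix columns, trajectory CSV columns and config/log entries.
#'
#' @return character vector of length 12.
#' @export
species_ids <- function() {
  c("mcp1", "mac", "tcell", "smc", "il6", "il10", "il12",
    "tnfa", "ifng", "mmp", "timp", "ecm")
}

.cell_species <- c("mac", "tcell", "smc")
.cytokine_species <- c("mcp1", "il6", "il10", "il12", "tnfa", "ifng",
                       "mmp", "timp")

.as_state_matrix <- function(z) {
  ids <- species_ids()
  if (is.numeric(z) && is.null(dim(z))) z <- matrix(z, nrow = 1,
                                                    dimnames = list(NULL, names(z)))
  z <- as.matrix(z)
  if (!all(ids %in% colnames(z))) {
    stop("state must have columns ", paste(ids, collapse = ", "), call. = FALSE)
  }
  z[, ids, drop = FALSE]
}

#' Production terms and (implicit-ready) decay coefficients
#'
#' Splits the reaction right-hand side of each species into a nonnegative
#' production part and a linear decay coefficient, so that
#' `F = production - decay * z`. The decay coefficients absorb the
#' state-dependent loss channels (MCP-1 internalization, SMC apoptosis by
#' macrophages, MMP/TIMP mutual binding, ECM degradation by MMP) evaluated
#' at the supplied state; the transport solver freezes them at the previous
#' time level and treats them implicitly.
#'
#' @param z numeric matrix (points x 12) with columns named as
#'   [species_ids()], or a named numeric vector for a single point.
#' @param params an [aaa_params][load_parameters] object.
#' @param subdomain `"media"` or `"adventitia"`, scalar or one per row.
#' @return list with matrices `production` and `decay` (same shape as `z`).
#' @export
reaction_split <- function(z, params, subdomain = "media") {
  z <- .as_state_matrix(z)
  if (any(z < 0)) {
    bad <- colnames(z)[which(z < 0, arr.ind = TRUE)[1, 2]]
    stop("negative concentration in species ", bad,
         " (clamp before evaluating kinetics)", call. = FALSE)
  }
  n <- nrow(z)
  sub <- rep_len(subdomain, n)
  in_media <- sub == "media"
  chiA <- as.numeric(!in_media)
  p <- params
  P <- z[, "mcp1"]; M <- z[, "mac"]; Tc <- z[, "tcell"]
  S <- ifelse(in_media, z[, "smc"], 0)   # SMCs exist only in the media
  I6 <- z[, "il6"]; I10 <- z[, "il10"]; I12 <- z[, "il12"]
  Ta <- z[, "tnfa"]; Ig <- z[, "ifng"]; Q <- z[, "mmp"]; Qr <- z[, "timp"]
  rho <- z[, "ecm"]
  fM <- M / (M + p$K_M)              # macrophage saturation factor
  inh10 <- 1 / (1 + I10 / p$K_I10)   # IL-10 inhibition
  enhTa <- 1 + p$lambda_MTa * Ta / (Ta + p$K_Ta)
  enhQTa <- 1 + p$lambda_QTa * Ta / (Ta + p$K_Ta)

  production <- cbind(
    mcp1 = p$lambda_PS * fM * S,
    mac  = p$lambda_MIg * M * Ig / (Ig + p$K_Ig) * enhTa,
    tcell = p$lambda_T * I12 * inh10 * M,
    smc  = ifelse(in_media, p$lambda_S, 0),
    il6  = p$lambda_I6M * M + p$lambda_I6S * S,
    il10 = p$lambda_I10M * M,
    il12 = p$lambda_I12M * M * inh10,
    tnfa = p$lambda_TaM * M * inh10,
    ifng = p$lambda_IgT * Tc,
    mmp  = (p$lambda_QM * M + p$lambda_QS * S) * enhQTa,
    timp = p$lambda_QrM * M,
    ecm  = (p$lambda_rf * chiA + p$lambda_rS * S) * pmax(1 - rho / p$rho0, 0)
  )
  decay <- cbind(
    mcp1 = p$d_P + p$d_PM * M / (P + p$K_P),
    mac  = rep_len(p$d_M, n),
    tcell = rep_len(p$d_T, n),
    smc  = ifelse(in_media, p$d_S + p$d_SM * fM, 0),
    il6  = rep_len(p$d_I6, n),
    il10 = rep_len(p$d_I10, n),
    il12 = rep_len(p$d_I12, n),
    tnfa = rep_len(p$d_Ta, n),
    ifng = rep_len(p$d_Ig, n),
    mmp  = p$d_Q + p$d_QQr * Qr,
    timp = p$d_Qr + p$d_QrQ * Q,
    ecm  = p$d_r + p$d_rQ * Q
  )
  # SMCs exist only in the media; their state is carried as 0 elsewhere
  production[!in_media, "smc"] <- 0
  list(production = production, decay = decay)
}

#' Pointwise reaction source terms for the species network
#'
#' Evaluates the non-transport right-hand side F(Z) of all twelve species
#' equations: MCP-1 production by macrophage-induced apoptotic SMCs,
#' internalization and decay; macrophage activation by IFN-gamma enhanced by
#' TNF-alpha, and death; T-cell activation by macrophage contact in an
#' IL-12 environment inhibited by IL-10; SMC source, apoptosis and death
#' (media only); cytokine production/decay with the IL-10 inhibitions;
#' MMP/TIMP production, mutual binding depletion and decay; and ECM
#' production with the saturation clamp `(1 - rho/rho0)^+` and degradation
#' by MMP.
#'
#' @inheritParams reaction_split
#' @return numeric matrix (points x 12) of rates in g cm^-3 day^-1.
#' @examples
#' z <- stats::setNames(numeric(12), species_ids())
#' z["mac"] <- 1e-3; z["il6"] <- 1e-8
#' reaction_rates(z, load_parameters())[, "il6"]  # 0: assay steady state
#' @export
reaction_rates <- function(z, params, subdomain = "media") {
  s <- reaction_split(z, params, subdomain)
  s$production - s$decay * .as_state_matrix(z)
}

#' Chemotactic flux of macrophages
#'
#' Keller-Segel-type flux `M * chi_C * (grad P + grad I6)` of macrophages up
#' the MCP-1 and IL-6 gradients; the transport operator subtracts its
#' divergence. MCP-1 and IL-6 share the chemotactic coefficient.
#'
#' @param M macrophage density (g/cm^3), length-n vector.
#' @param grad_P,grad_I6 n x 2 gradient matrices (g/cm^4).
#' @param chi_C chemotactic coefficient (cm^5 g^-1 day^-1).
#' @return n x 2 flux matrix (g cm^-2 day^-1).
#' @export
chemotactic_flux <- function(M, grad_P, grad_I6, chi_C) {
  grad_P <- rbind(grad_P); grad_I6 <- rbind(grad_I6)
  stopifnot(all(is.finite(grad_P)), all(is.finite(grad_I6)))
  out <- M * chi_C * (grad_P + grad_I6)
  dimnames(out) <- NULL
  out
}

#' Robin boundary/interface transfer coefficients
#'
#' Encodes every boundary and interface condition of the species network as
#' an exchange law `flux = -rate * (X - external)`: macrophage and T-cell
#' influx on the blood-side and outer boundaries (the macrophage rate is
#' gated by local MCP-1, `alpha_M(P) = alpha_M * P/(P + K_P)`), MCP-1 and
#' IL-6 endothelial sources on the blood side only, and media/adventitia
#' exchange across the interface with class-specific coefficients (50 for
#' cells, 500 for cytokines). SMCs get zero flux at the interface; ECM is
#' transmitted continuously (a single shared field, signalled by an infinite
#' rate); every unspecified pair is zero-flux.
#'
#' The rates act as exchange velocities in the weak form (the boundary
#' integrals carry no diffusion-coefficient factor), matching the discrete
#' scheme.
#'
#' @param species one of [species_ids()].
#' @param boundary one of `"gammaB"`, `"gammaA"`, `"gammaM_media"`,
#'   `"gammaM_adventitia"`.
#' @param params an [aaa_params][load_parameters] object.
#' @param z_local named numeric state on this side (needed for the
#'   MCP-1-gated macrophage rate; defaults to zeros).
#' @param z_across named numeric state on the far side of the interface
#'   (supplies the external value at `gammaM_*`).
#' @return list with `rate` (cm^-1, acting as cm/day in the weak form;
#'   `Inf` marks a continuously transmitted field) and `external` (g/cm^3;
#'   `NA` where irrelevant).
#' @export
robin_coefficients <- function(species, boundary, params,
                               z_local = NULL, z_across = NULL) {
  ids <- species_ids()
  if (!species %in% ids) stop("unknown species id: ", species, call. = FALSE)
  bids <- c("gammaB", "gammaA", "gammaM_media", "gammaM_adventitia")
  if (!boundary %in% bids) stop("unknown boundary id: ", boundary, call. = FALSE)
  p <- params
  zero <- list(rate = 0, external = NA_real_)
  if (boundary %in% c("gammaM_media", "gammaM_adventitia")) {
    if (species == "smc") return(zero)
    if (species == "ecm") return(list(rate = Inf, external = NA_real_))
    g <- if (species %in% .cell_species) p$gamma_cell else p$gamma_cytokine
    ext <- if (!is.null(z_across)) unname(z_across[species]) else NA_real_
    return(list(rate = g, external = ext))
  }
  if (species == "smc" && boundary == "gammaB") return(zero)
  if (species == "mac") {
    P <- if (!is.null(z_local)) unname(z_local["mcp1"]) else 0
    return(list(rate = p$alpha_M * P / (P + p$K_P), external = p$M0))
  }
  if (species == "tcell") return(list(rate = p$alpha_T, external = p$T0))
  if (boundary == "gammaB") {
    if (species == "mcp1") return(list(rate = p$alpha_P, external = p$P0))
    if (species == "il6") return(list(rate = p$alpha_I6, external = p$I60))
  }
  zero
}

#' Well-mixed two-compartment right-hand side
#'
#' Spatially homogeneous reduction of the full transport-reaction system:
#' each layer is one compartment; diffusion disappears, the interface
#' exchange becomes `gamma * sv * (X_other - X_this)` and the boundary
#' influx `alpha * sv * (X0 - X)`, with `sv` the surface-to-volume ratio of
#' the corresponding boundary (cm^-1). ECM has no interface exchange term
#' (it is quasi-immobile and continuous across the interface in the full
#' model).
#'
#' @param z_media,z_adventitia named numeric vectors (12 species, g/cm^3);
#'   `smc` is ignored in the adventitia.
#' @param params an [aaa_params][load_parameters] object.
#' @param sv named list of surface-to-volume ratios: `B` (Gamma_B / media
#'   area), `M_media`, `M_adv` (interface over each layer's area), `A`
#'   (Gamma_A / adventitia area), all in cm^-1.
#' @return list with numeric vectors `media` and `adventitia` (g cm^-3
#'   day^-1).
#' @export
wellmixed_rhs <- function(z_media, z_adventitia, params, sv) {
  stopifnot(all(unlist(sv) >= 0))
  ids <- species_ids()
  zm <- z_media[ids]; za <- z_adventitia[ids]
  za["smc"] <- 0
  fm <- drop(reaction_rates(zm, params, "media"))
  fa <- drop(reaction_rates(za, params, "adventitia"))
  p <- params
  gam <- stats::setNames(numeric(12), ids)
  gam[.cell_species] <- p$gamma_cell
  gam[.cytokine_species] <- p$gamma_cytokine
  gam["smc"] <- 0; gam["ecm"] <- 0
  ex_m <- gam * sv$M_media * (za - zm)
  ex_a <- gam * sv$M_adv * (zm - za)
  ex_m["smc"] <- 0; ex_a["smc"] <- 0
  # blood-side boundary (media): macrophages, T cells, MCP-1, IL-6
  aM_m <- p$alpha_M * zm["mcp1"] / (zm["mcp1"] + p$K_P)
  ex_m["mac"] <- ex_m["mac"] + sv$B * aM_m * (p$M0 - zm["mac"])
  ex_m["tcell"] <- ex_m["tcell"] + sv$B * p$alpha_T * (p$T0 - zm["tcell"])
  ex_m["mcp1"] <- ex_m["mcp1"] + sv$B * p$alpha_P * (p$P0 - zm["mcp1"])
  ex_m["il6"] <- ex_m["il6"] + sv$B * p$alpha_I6 * (p$I60 - zm["il6"])
  # outer boundary (adventitia): macrophages and T cells only
  aM_a <- p$alpha_M * za["mcp1"] / (za["mcp1"] + p$K_P)
  ex_a["mac"] <- ex_a["mac"] + sv$A * aM_a * (p$M0 - za["mac"])
  ex_a["tcell"] <- ex_a["tcell"] + sv$A * p$alpha_T * (p$T0 - za["tcell"])
  out_a <- fa + ex_a
  out_a["smc"] <- 0
  list(media = fm + ex_m, adventitia = out_a)
}
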