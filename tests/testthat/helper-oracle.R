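# Independent literal transcription of the twelve reaction equations,
# coded scalar-by-scalar from the model statement (kept deliberately
# separate from the package's vectorized implementation).
oracle_reaction_rates <- function(z, p, subdomain = "media") {
  P <- z[["mcp1"]]; M <- z[["mac"]]; Tc <- z[["tcell"]]
  S <- if (subdomain == "media") z[["smc"]] else 0
  I6 <- z[["il6"]]; I10 <- z[["il10"]]; I12 <- z[["il12"]]
  Ta <- z[["tnfa"]]; Ig <- z[["ifng"]]; Q <- z[["mmp"]]; Qr <- z[["timp"]]
  rho <- z[["ecm"]]
  chiA <- if (subdomain == "adventitia") 1 else 0
  plus <- function(x) if (x > 0) x else 0
  c(
    mcp1 = p$lambda_PS * (M / (M + p$K_M)) * S -
      p$d_PM * (P / (P + p$K_P)) * M - p$d_P * P,
    mac = p$lambda_MIg * M * (Ig / (Ig + p$K_Ig)) *
      (1 + p$lambda_MTa * Ta / (Ta + p$K_Ta)) - p$d_M * M,
    tcell = p$lambda_T * (I12 / (1 + I10 / p$K_I10)) * M - p$d_T * Tc,
    smc = if (subdomain == "media") {
      p$lambda_S - p$d_SM * (M / (M + p$K_M)) * S - p$d_S * S
    } else 0,
    il6 = p$lambda_I6M * M + p$lambda_I6S * S - p$d_I6 * I6,
    il10 = p$lambda_I10M * M - p$d_I10 * I10,
    il12 = p$lambda_I12M * M / (1 + I10 / p$K_I10) - p$d_I12 * I12,
    tnfa = p$lambda_TaM * M / (1 + I10 / p$K_I10) - p$d_Ta * Ta,
    ifng = p$lambda_IgT * Tc - p$d_Ig * Ig,
    mmp = (p$lambda_QM * M + p$lambda_QS * S) *
      (1 + p$lambda_QTa * Ta / (Ta + p$K_Ta)) -
      p$d_QQr * Qr * Q - p$d_Q * Q,
    timp = p$lambda_QrM * M - p$d_QrQ * Q * Qr - p$d_Qr * Qr,
    ecm = (p$lambda_rf * chiA + p$lambda_rS * S) * plus(1 - rho / p$rho0) -
      p$d_r * rho - p$d_rQ * Q * rho
  )
}

# random physiological-magnitude state
random_state <- function() {
  scales <- c(mcp1 = 1e-7, mac = 1e-4, tcell = 1e-3, smc = 1e-2,
              il6 = 1e-7, il10 = 1e-7, il12 = 1e-7, tnfa = 1e-7,
              ifng = 1e-9, mmp = 1e-7, timp = 1e-7, ecm = 1e-3)
  stats::setNames(stats::runif(12) * scales, names(scales))
}

# parameter set with every reaction, exchange and chemotaxis constant zeroed
zeroed_kinetics_params <- function(extra = list()) {
  d <- aortawall:::.aaa_defaults()
  keys <- grep("^(lambda_|d_|alpha_)", names(d), value = TRUE)
  ov <- stats::setNames(as.list(rep(0, length(keys))), keys)
  ov$gamma_cell <- 0
  ov$gamma_cytokine <- 0
  ov$chi_C <- 0
  load_parameters(utils::modifyList(ov, extra))
}

# minimal hand-built simulation state for direct advance_species calls
make_transport_state <- function(params, ny = 4, n_med = 2, n_adv = 1) {
  geom <- build_initial_geometry(R0 = 2, ny = ny, n_med = n_med,
                                 n_adv = n_adv)
  ids <- species_ids()
  zmed <- matrix(0, length(geom$med_nodes), 12, dimnames = list(NULL, ids))
  zadv <- matrix(0, length(geom$adv_nodes), 12, dimnames = list(NULL, ids))
  list(geom = geom, params = params, zmed = zmed, zadv = zadv,
       ecm = rep(0, nrow(geom$ref)), clamped_last = 0)
}
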