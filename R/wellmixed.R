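#' Well-mixed two-compartment reduction
#'
#' Spatially homogeneous version of the full model: one compartment per
#' wall layer, diffusion dropped, interface and boundary exchange scaled by
#' the surface-to-volume ratios of the reference geometry. Used for fast
#' verification, steady-state analysis and parameter sanity checks.
#'
#' @name wellmixed
NULL

.default_sv <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- geometry_ratios(build_initial_geometry(R0 = 2, ny = 16,
                                                       n_med = 2, n_adv = 1))
    }
    cache
  }
})

#' Initial two-compartment state
#'
#' The reported initial tissue state: IL-6 at half the serum influx level,
#' MMP, TIMP and ECM at their measured values, SMCs at baseline in the
#' media; all other species zero.
#'
#' @param params an [aaa_params][load_parameters] object.
#' @return named numeric vector of length 24 (`med_*`, `adv_*`).
#' @export
compartment_state <- function(params) {
  ids <- species_ids()
  z <- stats::setNames(numeric(12), ids)
  z["il6"] <- params$I60 / 2
  z["mmp"] <- params$Q_init
  z["timp"] <- params$Qr_init
  z["ecm"] <- params$rho_init
  zm <- z; zm["smc"] <- params$S0
  stats::setNames(c(zm, z), c(paste0("med_", ids), paste0("adv_", ids)))
}

.unpack_compartments <- function(y) {
  ids <- species_ids()
  list(media = stats::setNames(y[seq_len(12)], ids),
       adventitia = stats::setNames(y[12 + seq_len(12)], ids))
}

#' Integrate the well-mixed reduction
#'
#' Stiff-safe implicit integration (lsoda) of the 24-state compartment
#' system; negative undershoots are clamped to zero inside the right-hand
#' side evaluation.
#'
#' @param z0 named 24-vector from [compartment_state()] (or `NULL` for the
#'   default initial state).
#' @param params an [aaa_params][load_parameters] object.
#' @param T_end horizon (day).
#' @param k output sampling interval (day).
#' @param sv surface-to-volume ratios (see [wellmixed_rhs()]); defaults to
#'   the reference geometry's ratios.
#' @return data frame: `time` plus the 24 species columns.
#' @export
integrate_wellmixed <- function(z0 = NULL, params = load_parameters(),
                                T_end = 500, k = 1, sv = NULL) {
  stopifnot(k > 0, T_end >= 0)
  if (is.null(sv)) sv <- .default_sv()
  if (is.null(z0)) z0 <- compartment_state(params)
  deriv <- function(t, y, parms) {
    z <- .unpack_compartments(pmax(y, 0))
    r <- wellmixed_rhs(z$media, z$adventitia, params, sv)
    list(c(r$media, r$adventitia))
  }
  times <- seq(0, T_end, by = k)
  if (T_end == 0) times <- 0
  out <- deSolve::ode(y = z0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-14)
  if (attr(out, "istate")[1] < 0) {
    stop("well-mixed integration failed (lsoda istate = ",
         attr(out, "istate")[1], ")", call. = FALSE)
  }
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  df
}

#' Steady state of the well-mixed reduction
#'
#' Damped Newton iteration with a finite-difference Jacobian on the
#' compartment right-hand side. Components listed in `fixed` are clamped to
#' their guess value and removed from the unknowns (useful for closed-form
#' checks with, say, macrophages held constant).
#'
#' @param params an [aaa_params][load_parameters] object.
#' @param z_guess named 24-vector initial guess.
#' @param sv surface-to-volume ratios; set all to zero to switch exchange
#'   off.
#' @param fixed character vector of state names (e.g. `"med_mac"`) to hold
#'   fixed.
#' @param tol relative residual tolerance.
#' @return named 24-vector steady state (nonnegative).
#' @export
find_steady_state <- function(params, z_guess = NULL, sv = NULL,
                              fixed = character(0), tol = 1e-12) {
  if (is.null(sv)) sv <- .default_sv()
  if (is.null(z_guess)) z_guess <- compartment_state(params)
  y <- z_guess
  nm <- names(y)
  # the adventitia SMC slot is structurally zero
  fixed <- union(fixed, "adv_smc")
  act <- which(!nm %in% fixed)
  rhs <- function(yy) {
    z <- .unpack_compartments(pmax(yy, 0))
    r <- wellmixed_rhs(z$media, z$adventitia, params, sv)
    unname(c(r$media, r$adventitia))
  }
  nrm <- function(r) sqrt(sum(r^2))
  r0_norm <- nrm(rhs(y)[act])
  # converge on a 1e-12 relative residual reduction; the floor is the
  # round-off level of the rate expressions (production + decay term
  # magnitudes), below which the residual cannot be evaluated
  z <- .unpack_compartments(pmax(y, 0))
  sm <- reaction_split(z$media, params, "media")
  sa <- reaction_split(z$adventitia, params, "adventitia")
  tmag <- nrm(c(sm$production + sm$decay * .as_state_matrix(z$media),
                sa$production + sa$decay * .as_state_matrix(z$adventitia)))
  tol_abs <- max(tol * r0_norm, 1e-12 * tmag, 1e-280)
  for (it in seq_len(200)) {
    r <- rhs(y)[act]
    if (nrm(r) <= tol_abs) break
    J <- matrix(0, length(act), length(act))
    for (jj in seq_along(act)) {
      h <- max(1e-7 * abs(y[act[jj]]), 1e-12)
      yp <- y; yp[act[jj]] <- yp[act[jj]] + h
      if (y[act[jj]] - h >= 0) {
        ym <- y; ym[act[jj]] <- ym[act[jj]] - h
        J[, jj] <- (rhs(yp)[act] - rhs(ym)[act]) / (2 * h)
      } else {
        J[, jj] <- (rhs(yp)[act] - r) / h
      }
    }
    delta <- tryCatch(solve(J, -r), error = function(e) {
      stop("singular Jacobian in steady-state search; try a new guess",
           call. = FALSE)
    })
    lam <- 1
    for (dmp in 0:30) {
      y_try <- y
      y_try[act] <- pmax(y[act] + lam * delta, 0)
      r_try <- rhs(y_try)[act]
      if (nrm(r_try) < nrm(r) || dmp == 30) break
      lam <- lam / 2
    }
    y <- y_try
    if (it == 200) {
      stop("steady-state iteration diverged; try a new guess", call. = FALSE)
    }
  }
  pmax(y, 0)
}
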