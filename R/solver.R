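#' Decoupled time stepping for the coupled model
#'
#' Each time step of length `k` (days) executes the decoupled scheme:
#' (1) Newton solve of the Lagrangian hyperelastic equilibrium in the
#' reference domain, with moduli and pressure frozen at the previous-step
#' SMC and ECM fields; (2) mesh update by the flow map `x = x_ref + u`;
#' (3) implicit transport solve for the species on the moved mesh, with
#' implicit diffusion, the `div(v) Z` dilution term, Robin boundary and
#' interface exchange, lagged chemotaxis, explicit production and implicit
#' (lagged-coefficient) degradation. Because the mesh nodes follow the flow
#' map, the discrete material derivative needs no interpolation.
#'
#' @name aaa_solver
NULL

.default_newton_control <- function(control = list()) {
  utils::modifyList(list(atol = 1e-12, rtol = 1e-10, max_iter = 25L,
                         max_damping = 8L), control)
}

# merged-mesh SMC field seen by the moduli law
.smc_for_mechanics <- function(state) {
  geom <- state$geom
  s <- rep(state$params$adventitia_smc, nrow(geom$ref))
  s[geom$med_nodes] <- state$zmed[, "smc"]
  s
}

#' Newton solve of the hyperelastic equilibrium
#'
#' Solves the nonlinear Lagrangian residual for the displacement on the
#' reference mesh with the Gamma_0 clamp, using an analytic consistent
#' tangent and a simple backtracking damping safeguard. Converges when the
#' residual 2-norm falls below `max(atol, rtol * initial_norm)`.
#'
#' @param u0 n x 2 initial displacement guess.
#' @param geom a [wall_geometry][build_initial_geometry].
#' @param smc,rho nodal fields on the merged mesh (see
#'   [lagrangian_residual()]).
#' @param params an [aaa_params][load_parameters] object.
#' @param control list: `atol`, `rtol`, `max_iter`, `max_damping`.
#' @param dirichlet optional list `list(nodes =, values =)` replacing the
#'   default Gamma_0 clamp: the listed nodes are held at the given n_d x 2
#'   displacement values (used e.g. for manufactured-solution studies).
#' @param body_force optional body-force function (see
#'   [lagrangian_residual()]).
#' @return list with `u`, `iterations`, `residual_norms`, `converged`.
#' @export
newton_solve_displacement <- function(u0, geom, smc, rho, params,
                                      control = list(), dirichlet = NULL,
                                      body_force = NULL) {
  ctl <- .default_newton_control(control)
  n <- nrow(geom$ref)
  coef <- .mech_coefficients(geom, smc, rho, params)
  if (is.null(dirichlet)) {
    dirichlet <- list(nodes = geom$gamma0_nodes,
                      values = matrix(0, length(geom$gamma0_nodes), 2))
  }
  fixed <- sort(c(2 * (dirichlet$nodes - 1) + 1,
                  2 * (dirichlet$nodes - 1) + 2))
  free <- setdiff(seq_len(2 * n), fixed)
  u <- as.matrix(u0)
  u[dirichlet$nodes, ] <- dirichlet$values
  norms <- numeric(0)
  res_free <- function(uu) {
    asm <- .mech_assemble(uu, geom, coef, params, want_tangent = FALSE,
                          body_force = body_force)
    asm$R[free]
  }
  r <- res_free(u)
  norms <- sqrt(sum(r^2))
  tol <- max(ctl$atol, ctl$rtol * norms[1])
  it <- 0L
  while (norms[length(norms)] > tol) {
    if (it >= ctl$max_iter) {
      return(list(u = u, iterations = it, residual_norms = norms,
                  converged = FALSE))
    }
    asm <- .mech_assemble(u, geom, coef, params, want_tangent = TRUE,
                          body_force = body_force)
    Kff <- asm$K[free, free, drop = FALSE]
    delta <- as.numeric(Matrix::solve(Kff, -asm$R[free]))
    step_u <- matrix(0, n, 2)
    step_u[cbind((free + 1) %/% 2, 2 - free %% 2)] <- delta
    lam <- 1
    for (dmp in 0:ctl$max_damping) {
      u_try <- u + lam * step_u
      ok <- TRUE
      r_try <- tryCatch(res_free(u_try), error = function(e) {
        ok <<- FALSE; NULL
      })
      if (ok && (sqrt(sum(r_try^2)) < norms[length(norms)] ||
                   sqrt(sum(r_try^2)) <= tol)) break
      lam <- lam / 2
      if (dmp == ctl$max_damping) {
        u_try <- u + lam * step_u
        r_try <- res_free(u_try)
      }
    }
    u <- u_try
    norms <- c(norms, sqrt(sum(r_try^2)))
    it <- it + 1L
  }
  list(u = u, iterations = it, residual_norms = norms, converged = TRUE)
}

# --- transport context: geometric arrays reused by every species ----------
.transport_context <- function(geom, v, k) {
  coords <- geom$coords
  sub_mesh <- function(nodes, g2l, keep) {
    tri_l <- matrix(g2l[geom$tri[keep, ]], ncol = 3)
    list(tri = tri_l, coords = coords[nodes, , drop = FALSE],
         n = length(nodes), keep = keep)
  }
  med <- sub_mesh(geom$med_nodes, geom$g2med, geom$sub == "media")
  adv <- sub_mesh(geom$adv_nodes, geom$g2adv, geom$sub == "adventitia")
  mrg <- list(tri = geom$tri, coords = coords, n = nrow(coords),
              keep = rep(TRUE, nrow(geom$tri)))
  build <- function(msh, vloc) {
    g <- .p1_geometry(msh$tri, msh$coords)
    A <- g$area
    lump <- .accumulate(rep(A / 3, 3), as.vector(msh$tri), msh$n)
    divv <- rep(0, nrow(msh$tri))
    for (a in 1:3) {
      divv <- divv + vloc[msh$tri[, a], 1] * g$gx[, a] +
        vloc[msh$tri[, a], 2] * g$gy[, a]
    }
    divlump <- .accumulate(rep(A / 3 * divv, 3), as.vector(msh$tri), msh$n)
    ki <- integer(9 * nrow(msh$tri)); kj <- ki; kx <- numeric(length(ki))
    pos <- 0L
    for (a in 1:3) for (b in 1:3) {
      idx <- pos + seq_len(nrow(msh$tri))
      ki[idx] <- msh$tri[, a]; kj[idx] <- msh$tri[, b]
      kx[idx] <- A * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b])
      pos <- pos + nrow(msh$tri)
    }
    list(g = g, area = A, lump = lump, divlump = divlump,
         ki = ki, kj = kj, kx = kx, tri = msh$tri, n = msh$n)
  }
  vmed <- v[geom$med_nodes, , drop = FALSE]
  vadv <- v[geom$adv_nodes, , drop = FALSE]
  ctx <- list(
    med = build(med, vmed), adv = build(adv, vadv), mrg = build(mrg, v),
    k = k
  )
  # current-configuration boundary nodal weights (half edge lengths)
  chain_w <- function(nodes) {
    p <- coords[nodes, , drop = FALSE]
    len <- sqrt(rowSums(diff(p)^2))
    w <- numeric(length(nodes))
    w[-length(w)] <- w[-length(w)] + len / 2
    w[-1] <- w[-1] + len / 2
    w
  }
  ctx$wB <- chain_w(geom$gammaB_nodes)            # on Gamma_B (media side)
  ctx$wA <- chain_w(geom$gammaA_nodes)            # on Gamma_A (adventitia)
  ctx$wM <- chain_w(geom$gammaM_nodes)            # interface
  ctx$gB_med <- geom$g2med[geom$gammaB_nodes]
  ctx$gA_adv <- geom$g2adv[geom$gammaA_nodes]
  ctx$gM_med <- geom$g2med[geom$gammaM_nodes]
  ctx$gM_adv <- geom$g2adv[geom$gammaM_nodes]
  # periodic identification maps per index space
  ctx$pmap_mrg <- geom$pmap
  ctx$pmap_med <- geom$g2med[geom$pmap[geom$med_nodes]]
  ctx$pmap_adv <- geom$g2adv[geom$pmap[geom$adv_nodes]]
  ctx
}

# solve A x = b with periodic identification given by map (map[i] is the
# representative index of unknown i); duplicated rows are summed.
.solve_folded <- function(i, j, x, b, map) {
  n <- length(map)
  reps <- which(map == seq_len(n))
  relabel <- integer(n)
  relabel[reps] <- seq_along(reps)
  idx <- relabel[map]
  A <- Matrix::sparseMatrix(i = idx[i], j = idx[j], x = x,
                            dims = c(length(reps), length(reps)))
  bb <- .accumulate(b, idx, length(reps))
  sol <- as.numeric(Matrix::solve(A, bb))
  sol[idx]
}

# chemotaxis right-hand side for macrophages on one sub-mesh:
# + int M chi (grad P + grad I6) . grad W
.chemo_rhs <- function(ct, Mv, Pv, I6v, chi) {
  tri <- ct$tri; g <- ct$g
  gPx <- gPy <- gIx <- gIy <- Mbar <- 0
  for (a in 1:3) {
    gPx <- gPx + Pv[tri[, a]] * g$gx[, a]
    gPy <- gPy + Pv[tri[, a]] * g$gy[, a]
    gIx <- gIx + I6v[tri[, a]] * g$gx[, a]
    gIy <- gIy + I6v[tri[, a]] * g$gy[, a]
    Mbar <- Mbar + Mv[tri[, a]] / 3
  }
  fx <- chi * Mbar * (gPx + gIx)
  fy <- chi * Mbar * (gPy + gIy)
  rhs <- numeric(ct$n)
  for (a in 1:3) {
    rhs <- rhs + .accumulate(ct$area * (fx * g$gx[, a] + fy * g$gy[, a]),
                             tri[, a], ct$n)
  }
  rhs
}

#' Advance the species one time step on the moved mesh
#'
#' Implicit transport solve per species following the discrete weak form:
#' lumped-mass material derivative, implicit `div(v) Z` dilution, implicit
#' diffusion, Robin interface coupling between the media and adventitia
#' copies, Robin boundary influx (macrophage rate gated by lagged MCP-1),
#' lagged chemotaxis for macrophages, explicit production and implicit
#' lagged-coefficient degradation. SMCs are solved in the media only; ECM is
#' a single continuous field on the merged mesh. Solutions are clamped to
#' zero from below and the clamped mass is recorded.
#'
#' @param state simulation state (see [run_simulation()]).
#' @param v n x 2 discrete velocity on the merged mesh (cm/day).
#' @param k time step (day).
#' @return updated state with new species fields and clamp diagnostics.
#' @export
advance_species <- function(state, v, k) {
  geom <- state$geom
  p <- state$params
  ctx <- .transport_context(geom, v, k)
  ids <- species_ids()
  zmed <- state$zmed; zadv <- state$zadv
  # keep the shared ECM view in sync before evaluating kinetics
  zmed[, "ecm"] <- state$ecm[geom$med_nodes]
  zadv[, "ecm"] <- state$ecm[geom$adv_nodes]
  sp_med <- reaction_split(zmed, p, "media")
  sp_adv <- reaction_split(zadv, p, "adventitia")

  D <- c(mcp1 = p$D_P, mac = p$D_M, tcell = p$D_T, smc = p$D_S,
         il6 = p$D_I6, il10 = p$D_I10, il12 = p$D_I12, tnfa = p$D_Ta,
         ifng = p$D_Ig, mmp = p$D_Q, timp = p$D_Qr, ecm = p$D_r)
  gam <- stats::setNames(numeric(12), ids)
  gam[.cell_species] <- p$gamma_cell
  gam[.cytokine_species] <- p$gamma_cytokine
  gam["smc"] <- 0; gam["ecm"] <- 0

  nm <- ctx$med$n; na <- ctx$adv$n
  # boundary Robin rates per species (lagged MCP-1 gates macrophages)
  rateB <- function(sid) {
    switch(sid,
      mac = {
        P <- zmed[ctx$gB_med, "mcp1"]
        p$alpha_M * P / (P + p$K_P)
      },
      tcell = rep(p$alpha_T, length(ctx$gB_med)),
      mcp1 = rep(p$alpha_P, length(ctx$gB_med)),
      il6 = rep(p$alpha_I6, length(ctx$gB_med)),
      rep(0, length(ctx$gB_med)))
  }
  extB <- c(mac = p$M0, tcell = p$T0, mcp1 = p$P0, il6 = p$I60)
  rateA <- function(sid) {
    switch(sid,
      mac = {
        P <- zadv[ctx$gA_adv, "mcp1"]
        p$alpha_M * P / (P + p$K_P)
      },
      tcell = rep(p$alpha_T, length(ctx$gA_adv)),
      rep(0, length(ctx$gA_adv)))
  }
  extA <- c(mac = p$M0, tcell = p$T0)

  chemo_med <- NULL; chemo_adv <- NULL
  clamped <- 0
  new_med <- zmed; new_adv <- zadv
  pmap2 <- c(ctx$pmap_med, nm + ctx$pmap_adv)

  jump_ids <- setdiff(ids, c("smc", "ecm"))
  for (sid in jump_ids) {
    dm <- ctx$med; da <- ctx$adv
    diag_m <- dm$lump / k + dm$divlump + dm$lump * sp_med$decay[, sid]
    diag_a <- da$lump / k + da$divlump + da$lump * sp_adv$decay[, sid]
    ii <- c(seq_len(nm), nm + seq_len(na), dm$ki, nm + da$ki)
    jj <- c(seq_len(nm), nm + seq_len(na), dm$kj, nm + da$kj)
    xx <- c(diag_m, diag_a, D[[sid]] * dm$kx, D[[sid]] * da$kx)
    # interface exchange, lumped edge mass
    if (gam[[sid]] > 0) {
      gm <- ctx$gM_med; ga <- nm + ctx$gM_adv
      w <- gam[[sid]] * ctx$wM
      ii <- c(ii, gm, gm, ga, ga)
      jj <- c(jj, gm, ga, ga, gm)
      xx <- c(xx, w, -w, w, -w)
    }
    rhs <- c(dm$lump / k * zmed[, sid] + dm$lump * sp_med$production[, sid],
             da$lump / k * zadv[, sid] + da$lump * sp_adv$production[, sid])
    rB <- rateB(sid)
    if (any(rB > 0)) {
      nb <- ctx$gB_med
      ii <- c(ii, nb); jj <- c(jj, nb); xx <- c(xx, ctx$wB * rB)
      rhs[nb] <- rhs[nb] + ctx$wB * rB * extB[[sid]]
    }
    rA <- rateA(sid)
    if (any(rA > 0)) {
      nb <- nm + ctx$gA_adv
      ii <- c(ii, nb); jj <- c(jj, nb); xx <- c(xx, ctx$wA * rA)
      rhs[nb] <- rhs[nb] + ctx$wA * rA * extA[[sid]]
    }
    if (sid == "mac") {
      if (is.null(chemo_med)) {
        chemo_med <- .chemo_rhs(ctx$med, zmed[, "mac"], zmed[, "mcp1"],
                                zmed[, "il6"], p$chi_C)
        chemo_adv <- .chemo_rhs(ctx$adv, zadv[, "mac"], zadv[, "mcp1"],
                                zadv[, "il6"], p$chi_C)
      }
      rhs <- rhs + c(chemo_med, chemo_adv)
    }
    sol <- .solve_folded(ii, jj, xx, rhs, pmap2)
    xm <- sol[seq_len(nm)]; xa <- sol[nm + seq_len(na)]
    clamped <- clamped + sum(ctx$med$lump * pmax(-xm, 0)) +
      sum(ctx$adv$lump * pmax(-xa, 0))
    new_med[, sid] <- pmax(xm, 0)
    new_adv[, sid] <- pmax(xa, 0)
  }
  # SMCs: media only, zero-flux everywhere
  {
    dm <- ctx$med
    diag_m <- dm$lump / k + dm$divlump + dm$lump * sp_med$decay[, "smc"]
    ii <- c(seq_len(nm), dm$ki); jj <- c(seq_len(nm), dm$kj)
    xx <- c(diag_m, D[["smc"]] * dm$kx)
    rhs <- dm$lump / k * zmed[, "smc"] + dm$lump * sp_med$production[, "smc"]
    sol <- .solve_folded(ii, jj, xx, rhs, ctx$pmap_med)
    clamped <- clamped + sum(dm$lump * pmax(-sol, 0))
    new_med[, "smc"] <- pmax(sol, 0)
  }
  # ECM: single continuous field on the merged mesh
  {
    mg <- ctx$mrg
    n <- mg$n
    Qm <- rep(0, n)
    Qm[geom$med_nodes] <- zmed[, "mmp"]
    Qa <- rep(NA_real_, n); Qa[geom$adv_nodes] <- zadv[, "mmp"]
    only_adv <- setdiff(geom$adv_nodes, geom$med_nodes)
    Qm[only_adv] <- Qa[only_adv]
    iface <- intersect(geom$med_nodes, geom$adv_nodes)
    Qm[iface] <- (Qm[iface] + Qa[iface]) / 2
    decay <- p$d_r + p$d_rQ * Qm
    diag_m <- mg$lump / k + mg$divlump + mg$lump * decay
    ii <- c(seq_len(n), mg$ki); jj <- c(seq_len(n), mg$kj)
    xx <- c(diag_m, D[["ecm"]] * mg$kx)
    # production assembled element-wise (chi_A is an element property)
    S_bio <- rep(0, n)
    S_bio[geom$med_nodes] <- zmed[, "smc"]
    rho <- state$ecm
    prod_rhs <- numeric(n)
    is_adv <- geom$sub == "adventitia"
    for (a in 1:3) {
      nd <- geom$tri[, a]
      coefs <- ifelse(is_adv, p$lambda_rf, p$lambda_rS * S_bio[nd])
      val <- mg$area / 3 * coefs * pmax(1 - rho[nd] / p$rho0, 0)
      prod_rhs <- prod_rhs + .accumulate(val, nd, n)
    }
    rhs <- mg$lump / k * rho + prod_rhs
    sol <- .solve_folded(ii, jj, xx, rhs, ctx$pmap_mrg)
    clamped <- clamped + sum(mg$lump * pmax(-sol, 0))
    state$ecm <- pmax(sol, 0)
  }
  new_med[, "ecm"] <- state$ecm[geom$med_nodes]
  new_adv[, "ecm"] <- state$ecm[geom$adv_nodes]
  state$zmed <- new_med
  state$zadv <- new_adv
  state$clamped_last <- clamped
  state
}

# layer-wise area-weighted averages of the current species fields
.layer_averages <- function(state) {
  geom <- state$geom
  avg <- function(tri_keep, field_global) {
    tri <- geom$tri[tri_keep, , drop = FALSE]
    A <- .tri_areas(tri, geom$coords)
    f <- (field_global[tri[, 1]] + field_global[tri[, 2]] +
            field_global[tri[, 3]]) / 3
    sum(A * f) / sum(A)
  }
  ids <- species_ids()
  med_keep <- geom$sub == "media"; adv_keep <- !med_keep
  out <- numeric(0)
  for (sid in ids) {
    fm <- rep(0, nrow(geom$ref)); fm[geom$med_nodes] <- state$zmed[, sid]
    fa <- rep(0, nrow(geom$ref)); fa[geom$adv_nodes] <- state$zadv[, sid]
    out[paste0(sid, "_media")] <- avg(med_keep, fm)
    out[paste0(sid, "_adventitia")] <- avg(adv_keep, fa)
  }
  out
}

#' Initialize the simulation state
#'
#' Builds the geometry, sets the initial species fields (IL-6 at half its
#' serum influx level, MMP/TIMP/ECM/SMC at their reported tissue values, all
#' other cells and cytokines zero), and performs the t = 0 pre-equilibration
#' solve of the mechanics under the initial loads; the reported diameter is
#' scaled so that R(0) equals the configured `R0` exactly.
#'
#' @param params an [aaa_params][load_parameters] object.
#' @param R0 initial bulge diameter (cm).
#' @param ny,n_med,n_adv mesh resolution (see [build_initial_geometry()]).
#' @param newton_control see [newton_solve_displacement()].
#' @return a simulation state list.
#' @export
simulation_init <- function(params, R0 = 2, ny = 32, n_med = 4, n_adv = 2,
                            newton_control = list()) {
  geom <- build_initial_geometry(R0 = R0, ny = ny, n_med = n_med,
                                 n_adv = n_adv)
  ids <- species_ids()
  zmed <- matrix(0, length(geom$med_nodes), 12, dimnames = list(NULL, ids))
  zadv <- matrix(0, length(geom$adv_nodes), 12, dimnames = list(NULL, ids))
  zmed[, "il6"] <- params$I60 / 2; zadv[, "il6"] <- params$I60 / 2
  zmed[, "mmp"] <- params$Q_init; zadv[, "mmp"] <- params$Q_init
  zmed[, "timp"] <- params$Qr_init; zadv[, "timp"] <- params$Qr_init
  zmed[, "smc"] <- params$S0
  ecm <- rep(params$rho_init, nrow(geom$ref))
  zmed[, "ecm"] <- ecm[geom$med_nodes]; zadv[, "ecm"] <- ecm[geom$adv_nodes]
  state <- list(geom = geom, params = params, time = 0, n_step = 0L,
                u = matrix(0, nrow(geom$ref), 2),
                u_prev = matrix(0, nrow(geom$ref), 2),
                zmed = zmed, zadv = zadv, ecm = ecm,
                clamped_last = 0, newton_control = newton_control)
  # t = 0 pre-equilibration under the initial loads
  smc_mech <- .smc_for_mechanics(state)
  ns <- newton_solve_displacement(state$u, geom, smc_mech, ecm, params,
                                  newton_control)
  if (!ns$converged) stop("pre-equilibration Newton solve did not converge",
                          call. = FALSE)
  state$u <- ns$u
  state$u_prev <- ns$u
  state$geom <- move_mesh(geom, ns$u)
  state$newton_last <- ns$iterations
  state$diameter_scale <- R0 / measure_diameter(state$geom)
  state
}

#' Execute one coupled time step
#'
#' Newton displacement solve (previous-step biology in the coefficients),
#' mesh update, species transport solve, clamp. On Newton failure or
#' element inversion the interval is retried with halved sub-steps (up to 5
#' halvings), after which the step aborts.
#'
#' @param state simulation state from [simulation_init()].
#' @param k time step (day).
#' @param depth internal recursion depth of the halving retry.
#' @return updated state.
#' @export
step_simulation <- function(state, k, depth = 0L) {
  attempt <- function(state, k) {
    p <- state$params
    smc_mech <- .smc_for_mechanics(state)
    ns <- newton_solve_displacement(state$u, state$geom, smc_mech,
                                    state$ecm, p, state$newton_control)
    if (!ns$converged) stop("Newton iteration did not converge",
                            call. = FALSE)
    geom_new <- move_mesh(state$geom, ns$u)
    v <- (ns$u - state$u) / k
    state$u_prev <- state$u
    state$u <- ns$u
    state$geom <- geom_new
    state$newton_last <- ns$iterations
    state <- advance_species(state, v, k)
    state$time <- state$time + k
    state$n_step <- state$n_step + 1L
    state
  }
  out <- tryCatch(attempt(state, k), error = function(e) e)
  if (!inherits(out, "error")) return(out)
  if (depth >= 5L) {
    stop("time step failed after 5 halvings at t = ", state$time, ": ",
         conditionMessage(out), call. = FALSE)
  }
  state <- step_simulation(state, k / 2, depth + 1L)
  step_simulation(state, k / 2, depth + 1L)
}

#' Run the coupled aneurysm growth simulation
#'
#' Simulates diameter growth from initial diameter `R0` under serum IL-6
#' level `I60` for `T_end` days, recording the bulge diameter and the
#' layer-wise spatial average of every species at each step.
#'
#' @param R0 initial bulge diameter (cm).
#' @param I60 serum IL-6 level (g/cm^3); overrides the parameter registry.
#' @param T_end simulation horizon (day).
#' @param params optional [aaa_params][load_parameters] object (built from
#'   defaults if omitted).
#' @param k time step (day).
#' @param ny,n_med,n_adv mesh resolution.
#' @param record_every record one trajectory row every this many steps.
#' @param newton_control see [newton_solve_displacement()].
#' @param snapshot_times times (day) at which to keep full field snapshots.
#' @return an `aaa_trajectory`: data frame with columns `time`, `diameter`,
#'   one `<species>_<layer>` column per species and layer, and diagnostics
#'   (`newton_iters`, `clamped_mass`); attributes carry the parameters, the
#'   final state and any snapshots. If the run aborts (e.g. a modulus
#'   becomes non-positive), the partial trajectory is returned with
#'   attribute `aborted` holding the message.
#' @export
run_simulation <- function(R0 = 2, I60 = NULL, T_end = 500, params = NULL,
                           k = 0.5, ny = 32, n_med = 4, n_adv = 2,
                           record_every = 1L, newton_control = list(),
                           snapshot_times = numeric(0)) {
  if (is.null(params)) params <- load_parameters()
  if (!is.null(I60)) {
    ov <- attr(params, "provenance")
    params$I60 <- I60
    ov["I60"] <- "override"
    attr(params, "provenance") <- ov
  }
  stopifnot(T_end >= 0, k > 0)
  state <- simulation_init(params, R0 = R0, ny = ny, n_med = n_med,
                           n_adv = n_adv, newton_control = newton_control)
  rowfun <- function(state) {
    c(time = state$time,
      diameter = measure_diameter(state$geom) * state$diameter_scale,
      .layer_averages(state),
      newton_iters = as.numeric(state$newton_last),
      clamped_mass = state$clamped_last)
  }
  rows <- list(rowfun(state))
  snapshots <- list()
  aborted <- NULL
  n_steps <- ceiling(T_end / k)
  if (n_steps > 0) {
    for (n in seq_len(n_steps)) {
      state2 <- tryCatch(step_simulation(state, k),
                         error = function(e) e)
      if (inherits(state2, "error")) {
        aborted <- conditionMessage(state2)
        break
      }
      state <- state2
      if (n %% record_every == 0 || n == n_steps) {
        rows[[length(rows) + 1]] <- rowfun(state)
      }
      if (length(snapshot_times) &&
            any(abs(snapshot_times - state$time) < k / 2)) {
        snapshots[[sprintf("t%g", state$time)]] <- state
      }
    }
  }
  traj <- as.data.frame(do.call(rbind, rows))
  structure(traj,
            params = params, R0 = R0, final_state = state,
            diameter_scale = state$diameter_scale,
            snapshots = snapshots, aborted = aborted,
            class = c("aaa_trajectory", "data.frame"))
}

#' @export
print.aaa_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat("<aaa_trajectory> ", n, " records, t = ", x$time[1], " .. ",
      x$time[n], " day; diameter ", signif(x$diameter[1], 4), " -> ",
      signif(x$diameter[n], 4), " cm\n", sep = "")
  if (!is.null(attr(x, "aborted"))) {
    cat("  [aborted: ", attr(x, "aborted"), "]\n", sep = "")
  }
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param traj an `aaa_trajectory` (or the well-mixed time series).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
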