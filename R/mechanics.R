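#' Hyperelastic wall mechanics
#'
#' The wall is an incompressible-type, homogeneous, isotropic hyperelastic
#' solid with stored energy `W = beta1 (I_B - 3) + beta2 (I_B - 3)^2`, where
#' `I_B = tr(B)` is the first invariant of the left Cauchy-Green tensor
#' `B = F F^T`. The model is posed on a 2D section under plane strain: `F`
#' is augmented with a unit out-of-plane stretch, so `I_B = tr(B_2D) + 1`
#' and the `(I_B - 3)` terms are literal. The Cauchy stress is
#' `sigma = -p I + (2 beta1 + 4 beta2 (I_B - 3)) B` with the hydrostatic
#' pressure given by the ECM law and the moduli by the SMC law, so the
#' elastic strength of the wall degrades as smooth muscle cells die.
#'
#' @name wall_mechanics
NULL

#' Elastic moduli as a function of SMC density
#'
#' Affine degradation law `beta_i = beta_i0 + k_i (S/S0 - 1)`: moduli drop
#' as SMCs are lost. A non-positive modulus anywhere in the simulated range
#' is a run-level failure (the constitutive law is not defined there).
#'
#' @param S SMC density (g/cm^3), vectorized.
#' @param params an [aaa_params][load_parameters] object.
#' @return list with numeric vectors `beta1`, `beta2` (N/cm^2).
#' @examples
#' p <- load_parameters()
#' elastic_moduli(p$S0 / 2, p)  # beta1 = 2.2, beta2 = 146.1 N/cm^2
#' @export
elastic_moduli <- function(S, params) {
  stopifnot(all(S >= 0))
  r <- S / params$S0 - 1
  b1 <- params$beta10 + params$k1 * r
  b2 <- params$beta20 + params$k2 * r
  if (any(b1 <= 0) || any(b2 <= 0)) {
    bad <- S[which(b1 <= 0 | b2 <= 0)[1]]
    stop("elastic modulus non-positive at S = ", signif(bad, 6),
         " g/cm^3 (S/S0 = ", signif(bad / params$S0, 4),
         "); aborting", call. = FALSE)
  }
  list(beta1 = b1, beta2 = b2)
}

#' Tissue pressure as a function of ECM density
#'
#' Affine law `p(rho) = p* - beta_p (1 - rho/rho*)`: the hydrostatic tissue
#' pressure drops as the extracellular matrix is degraded.
#'
#' @param rho ECM density (g/cm^3), vectorized.
#' @param params an [aaa_params][load_parameters] object.
#' @return pressure in N/cm^2.
#' @export
ecm_pressure <- function(rho, params) {
  stopifnot(all(rho >= 0))
  params$p_star - params$beta_p * (1 - rho / params$rho_star)
}

#' Deformation state from a displacement gradient
#'
#' Kinematic quantities at a point: `F = I + grad(u)` (convention
#' `grad(u)[i, j] = d u_i / d x_j`), `B = F F^T`, `J = det F`, and the
#' plane-strain-augmented first invariant `I_B = tr(B) + 1`.
#'
#' @param grad_u 2 x 2 displacement gradient (dimensionless).
#' @return list `F`, `B`, `J`, `I_B`.
#' @export
deformation_state <- function(grad_u) {
  F <- diag(2) + grad_u
  B <- F %*% t(F)
  list(F = F, B = B, J = det(F), I_B = sum(diag(B)) + 1)
}

#' Cauchy stress of the hyperelastic wall
#'
#' `sigma = -p I + (2 beta1 + 4 beta2 (I_B - 3)) B`, symmetric by
#' construction. Rejects inverted states (J <= 0).
#'
#' @param def a [deformation_state()].
#' @param p hydrostatic pressure (N/cm^2).
#' @param beta1,beta2 moduli (N/cm^2).
#' @return 2 x 2 in-plane Cauchy stress (N/cm^2).
#' @export
cauchy_stress <- function(def, p, beta1, beta2) {
  if (def$J <= 0) stop("inverted deformation state (J <= 0)", call. = FALSE)
  -p * diag(2) + (2 * beta1 + 4 * beta2 * (def$I_B - 3)) * def$B
}

# sum values into a vector of length n at (possibly repeated) indices
.accumulate <- function(vals, idx, n) {
  out <- numeric(n)
  tab <- rowsum(vals, idx)
  out[as.integer(rownames(tab))] <- tab[, 1]
  out
}

# --- element-level kinematics, vectorized over elements -------------------
.elem_deformation <- function(tri, u, g) {
  ue1 <- u[tri[, 1], , drop = FALSE]
  ue2 <- u[tri[, 2], , drop = FALSE]
  ue3 <- u[tri[, 3], , drop = FALSE]
  # grad(u)[d, j] = sum_a u_a[d] * gN_a[j]
  H11 <- ue1[, 1] * g$gx[, 1] + ue2[, 1] * g$gx[, 2] + ue3[, 1] * g$gx[, 3]
  H12 <- ue1[, 1] * g$gy[, 1] + ue2[, 1] * g$gy[, 2] + ue3[, 1] * g$gy[, 3]
  H21 <- ue1[, 2] * g$gx[, 1] + ue2[, 2] * g$gx[, 2] + ue3[, 2] * g$gx[, 3]
  H22 <- ue1[, 2] * g$gy[, 1] + ue2[, 2] * g$gy[, 2] + ue3[, 2] * g$gy[, 3]
  F11 <- 1 + H11; F12 <- H12; F21 <- H21; F22 <- 1 + H22
  J <- F11 * F22 - F12 * F21
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22, J = J,
       IB = F11^2 + F12^2 + F21^2 + F22^2 + 1)
}

# First Piola-Kirchhoff stress entries per element.
# variant "energy": P = phi F - p cof(F),  phi = 2 b1 + 4 b2 (I_B - 3)
#   (exact gradient of the stored energy per reference volume; induces the
#   constitutive Cauchy stress up to O(J - 1) in the nearly-incompressible
#   regime)
# variant "paper":  P = J c F - p cof(F),  c = b1 + 2 b2 (I_B - 3)
#   (the halved-coefficient Lagrangian form, kept as a switch)
.elem_piola <- function(d, p_e, b1, b2, variant = "energy") {
  phi <- if (variant == "energy") {
    2 * b1 + 4 * b2 * (d$IB - 3)
  } else {
    d$J * (b1 + 2 * b2 * (d$IB - 3))
  }
  list(
    P11 = phi * d$F11 - p_e * d$F22,
    P12 = phi * d$F12 + p_e * d$F21,
    P21 = phi * d$F21 + p_e * d$F12,
    P22 = phi * d$F22 - p_e * d$F11,
    phi = phi
  )
}

# Boundary edge data for a node chain: edges, adjacent elements, outward
# reference unit normals (away from the adjacent element centroid), lengths.
.boundary_edges <- function(geom, nodes) {
  eb <- cbind(nodes[-length(nodes)], nodes[-1])
  be <- .edge_elements(geom$tri, eb)
  p1 <- geom$ref[eb[, 1], , drop = FALSE]
  p2 <- geom$ref[eb[, 2], , drop = FALSE]
  e <- p2 - p1
  len <- sqrt(rowSums(e^2))
  nrm <- cbind(e[, 2], -e[, 1]) / len
  ctr <- (geom$ref[geom$tri[be, 1], , drop = FALSE] +
            geom$ref[geom$tri[be, 2], , drop = FALSE] +
            geom$ref[geom$tri[be, 3], , drop = FALSE]) / 3
  mid <- (p1 + p2) / 2
  flip <- rowSums(nrm * (mid - ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  list(edges = eb, elems = be, normal = nrm, length = len)
}

# Find, for each boundary edge (node pairs), the adjacent element index.
.edge_elements <- function(tri, edges) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- c(key(tri[, 1], tri[, 2]), key(tri[, 2], tri[, 3]),
          key(tri[, 3], tri[, 1]))
  eid <- rep(seq_len(nrow(tri)), 3)
  m <- match(key(edges[, 1], edges[, 2]), ek)
  if (anyNA(m)) stop("boundary edge not found in triangulation", call. = FALSE)
  eid[m]
}

#' Surface tension boundary contributions
#'
#' Evaluates the Lagrangian pull-back of the curvature traction
#' `gamma kappa n` on a boundary polyline: the integrand
#' `gamma J |F^-T n| (tr(grad w F^-1) - n^T F^-1 grad w F^-1 F^-T n /
#' |F^-T n|^2)` is the tangential surface divergence of the test field on
#' the current curve, which for piecewise-linear elements integrates edge by
#' edge to the gradient of `gamma` times the current polyline length. The
#' returned nodal vectors are therefore exactly `gamma dL/dx`; on a
#' discrete circle they approximate `gamma (1/R) n` times the nodal edge
#' mass.
#'
#' @param ref_poly k x 2 reference polyline coordinates (consecutive mesh
#'   edges).
#' @param u k x 2 displacement of the polyline nodes.
#' @param gamma_surf surface tension coefficient (N/cm).
#' @return k x 2 matrix of nodal residual contributions (N).
#' @export
surface_tension_term <- function(ref_poly, u, gamma_surf) {
  x <- as.matrix(ref_poly) + as.matrix(u)
  k <- nrow(x)
  stopifnot(k >= 2)
  e <- diff(x)
  len <- sqrt(rowSums(e^2))
  if (any(len == 0)) stop("degenerate (zero-length) boundary edge",
                          call. = FALSE)
  t_hat <- e / len
  out <- matrix(0, k, 2)
  out[-k, ] <- out[-k, ] - gamma_surf * t_hat
  out[-1, ] <- out[-1, ] + gamma_surf * t_hat
  out
}

# Surface tension Hessian triplets: d^2 (gamma L)/dx^2 per edge.
.surface_tension_tangent <- function(x, nodes, gamma_surf) {
  e <- diff(x[nodes, , drop = FALSE])
  len <- sqrt(rowSums(e^2))
  t_hat <- e / len
  ne <- nrow(e)
  a <- nodes[-length(nodes)]; b <- nodes[-1]
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (d1 in 1:2) for (d2 in 1:2) {
    h <- gamma_surf * ((d1 == d2) - t_hat[, d1] * t_hat[, d2]) / len
    ii <- c(ii, 2 * (a - 1) + d1, 2 * (b - 1) + d1,
            2 * (a - 1) + d1, 2 * (b - 1) + d1)
    jj <- c(jj, 2 * (a - 1) + d2, 2 * (b - 1) + d2,
            2 * (b - 1) + d2, 2 * (a - 1) + d2)
    vv <- c(vv, h, h, -h, -h)
  }
  list(i = ii, j = jj, x = vv)
}

# Element moduli/pressure coefficients from nodal fields on the merged mesh.
.mech_coefficients <- function(geom, smc, rho, params) {
  tri <- geom$tri
  S_e <- (smc[tri[, 1]] + smc[tri[, 2]] + smc[tri[, 3]]) / 3
  rho_e <- (rho[tri[, 1]] + rho[tri[, 2]] + rho[tri[, 3]]) / 3
  mod <- elastic_moduli(S_e, params)
  list(b1 = mod$beta1, b2 = mod$beta2, p = ecm_pressure(rho_e, params))
}

# Assemble the Lagrangian equilibrium residual and (optionally) its
# tangent. Residual is a length-2n vector ordered (x1, y1, x2, y2, ...).
.mech_assemble <- function(u, geom, coef, params, want_tangent = FALSE,
                           body_force = NULL) {
  tri <- geom$tri
  n <- nrow(geom$ref)
  m <- nrow(tri)
  g <- .p1_geometry(tri, geom$ref)
  d <- .elem_deformation(tri, u, g)
  if (any(d$J <= 0)) {
    stop("element inversion in displacement state (element ",
         which(d$J <= 0)[1], ")", call. = FALSE)
  }
  variant <- params$piola_variant
  P <- .elem_piola(d, coef$p, coef$b1, coef$b2, variant)
  A <- g$area
  R <- numeric(2 * n)
  for (a in 1:3) {
    rx <- A * (P$P11 * g$gx[, a] + P$P12 * g$gy[, a])
    ry <- A * (P$P21 * g$gx[, a] + P$P22 * g$gy[, a])
    R <- R + .accumulate(c(rx, ry),
                         c(2 * (tri[, a] - 1) + 1, 2 * (tri[, a] - 1) + 2),
                         2 * n)
  }
  # blood traction -p_B I on Gamma_B, pulled back with Nanson's formula:
  # residual += p_B cof(F) n_ref * (edge length / 2) at each edge endpoint
  bd <- geom$bnd_gammaB
  be <- bd$elems
  p_B <- params$p_B
  cof11 <- d$F22[be]; cof12 <- -d$F21[be]
  cof21 <- -d$F12[be]; cof22 <- d$F11[be]
  tx <- p_B * (cof11 * bd$normal[, 1] + cof12 * bd$normal[, 2]) * bd$length / 2
  ty <- p_B * (cof21 * bd$normal[, 1] + cof22 * bd$normal[, 2]) * bd$length / 2
  for (endp in 1:2) {
    nd <- bd$edges[, endp]
    R <- R + .accumulate(c(tx, ty),
                         c(2 * (nd - 1) + 1, 2 * (nd - 1) + 2), 2 * n)
  }
  # surface tension on Gamma_B and Gamma_M (current configuration)
  if (params$gamma_surf > 0) {
    for (chain in list(geom$gammaB_nodes, geom$gammaM_nodes)) {
      st <- surface_tension_term(geom$ref[chain, , drop = FALSE],
                                 u[chain, , drop = FALSE], params$gamma_surf)
      R <- R + .accumulate(c(st[, 1], st[, 2]),
                           c(2 * (chain - 1) + 1, 2 * (chain - 1) + 2), 2 * n)
    }
  }
  if (!is.null(body_force)) {
    # edge-midpoint (degree-2) quadrature of the load functional
    x1 <- geom$ref[tri[, 1], , drop = FALSE]
    x2 <- geom$ref[tri[, 2], , drop = FALSE]
    x3 <- geom$ref[tri[, 3], , drop = FALSE]
    f12 <- t(apply((x1 + x2) / 2, 1, body_force))
    f23 <- t(apply((x2 + x3) / 2, 1, body_force))
    f31 <- t(apply((x3 + x1) / 2, 1, body_force))
    fv <- list((f12 + f31) / 2, (f12 + f23) / 2, (f23 + f31) / 2)
    for (a in 1:3) {
      R <- R - .accumulate(c(A / 3 * fv[[a]][, 1], A / 3 * fv[[a]][, 2]),
                           c(2 * (tri[, a] - 1) + 1, 2 * (tri[, a] - 1) + 2),
                           2 * n)
    }
  }
  if (!want_tangent) return(list(R = R))

  # ---- analytic tangent dP/dF contracted with basis gradients ----
  Fm <- list(d$F11, d$F12, d$F21, d$F22)
  cofF <- list(d$F22, -d$F21, -d$F12, d$F11)
  Fi <- function(dd, j2) Fm[[2 * (dd - 1) + j2]]
  cofi <- function(dd, j2) cofF[[2 * (dd - 1) + j2]]
  cc <- if (variant == "paper") coef$b1 + 2 * coef$b2 * (d$IB - 3) else NULL
  ii <- integer(36 * m); jj <- integer(36 * m); vv <- numeric(36 * m)
  pos <- 0L
  for (b in 1:3) for (e2 in 1:2) {
    gbx <- g$gx[, b]; gby <- g$gy[, b]
    FdF <- Fi(e2, 1) * gbx + Fi(e2, 2) * gby          # F : dF
    cofFdF <- cofi(e2, 1) * gbx + cofi(e2, 2) * gby   # cof(F) : dF
    for (a in 1:3) for (dd in 1:2) {
      gax <- g$gx[, a]; gay <- g$gy[, a]
      FgN <- Fi(dd, 1) * gax + Fi(dd, 2) * gay        # row dd of F . grad Na
      if (variant == "energy") {
        t1 <- 8 * coef$b2 * FdF * FgN
        t2 <- if (dd == e2) P$phi * (gbx * gax + gby * gay) else 0
      } else {
        t1 <- (cofFdF * cc + d$J * 4 * coef$b2 * FdF) * FgN
        t2 <- if (dd == e2) d$J * cc * (gbx * gax + gby * gay) else 0
      }
      # -p cof(dF) : only the off row of cof(dF) is nonzero
      t3 <- if (dd == e2) 0 else if (e2 == 1) {
        -coef$p * (-gby * gax + gbx * gay)   # row 2 of cof(dF) = (-gby, gbx)
      } else {
        -coef$p * (gby * gax - gbx * gay)    # row 1 of cof(dF) = (gby, -gbx)
      }
      idx <- pos + seq_len(m)
      ii[idx] <- 2 * (tri[, a] - 1) + dd
      jj[idx] <- 2 * (tri[, b] - 1) + e2
      vv[idx] <- A * (t1 + t2 + t3)
      pos <- pos + m
    }
  }
  # blood-load tangent: p_B cof(dF) n on the adjacent element
  bi <- integer(0); bj <- integer(0); bv <- numeric(0)
  for (b in 1:3) for (e2 in 1:2) {
    gbx <- g$gx[be, b]; gby <- g$gy[be, b]
    if (e2 == 1) {
      cdn1 <- numeric(length(be))
      cdn2 <- -gby * bd$normal[, 1] + gbx * bd$normal[, 2]
    } else {
      cdn1 <- gby * bd$normal[, 1] - gbx * bd$normal[, 2]
      cdn2 <- numeric(length(be))
    }
    for (endp in 1:2) {
      nd <- bd$edges[, endp]
      w <- bd$length / 2
      bi <- c(bi, 2 * (nd - 1) + 1, 2 * (nd - 1) + 2)
      bj <- c(bj, 2 * (tri[be, b] - 1) + e2, 2 * (tri[be, b] - 1) + e2)
      bv <- c(bv, p_B * cdn1 * w, p_B * cdn2 * w)
    }
  }
  sti <- integer(0); stj <- integer(0); stv <- numeric(0)
  if (params$gamma_surf > 0) {
    x_cur <- geom$ref + u
    for (chain in list(geom$gammaB_nodes, geom$gammaM_nodes)) {
      st <- .surface_tension_tangent(x_cur, chain, params$gamma_surf)
      sti <- c(sti, st$i); stj <- c(stj, st$j); stv <- c(stv, st$x)
    }
  }
  K <- Matrix::sparseMatrix(i = c(ii, bi, sti), j = c(jj, bj, stj),
                            x = c(vv, bv, stv), dims = c(2 * n, 2 * n))
  list(R = R, K = K)
}

#' Lagrangian equilibrium residual
#'
#' Assembles the pulled-back weak-form residual of the hyperelastic
#' equilibrium on the reference mesh: first Piola-Kirchhoff stress term,
#' blood traction `sigma_B = -p_B I` on Gamma_B (via Nanson's formula),
#' zero traction on Gamma_A, and surface tension on Gamma_B and Gamma_M.
#' The Gamma_0 clamp is applied by the solver, not here, so the raw
#' residual of any displacement state can be inspected.
#'
#' @param u n x 2 nodal displacement on the reference mesh.
#' @param geom a [wall_geometry][build_initial_geometry].
#' @param smc nodal SMC density seen by the moduli law (merged mesh;
#'   adventitia nodes should carry `params$adventitia_smc`).
#' @param rho nodal ECM density (merged mesh).
#' @param params an [aaa_params][load_parameters] object.
#' @param body_force optional function `f(x) -> c(fx, fy)` (N/cm^3) added as
#'   a manufactured-solution source.
#' @return n x 2 matrix of residual values against the nodal test fields (N).
#' @export
lagrangian_residual <- function(u, geom, smc, rho, params,
                                body_force = NULL) {
  coef <- .mech_coefficients(geom, smc, rho, params)
  out <- .mech_assemble(as.matrix(u), geom, coef, params,
                        want_tangent = FALSE, body_force = body_force)
  matrix(out$R, ncol = 2, byrow = TRUE)
}
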