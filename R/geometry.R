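#' Two-layer bulge geometry and moving mesh
#'
#' The reference configuration is a 2D section of the aneurysmal wall: two
#' nested curved strips (media between the blood-side boundary Gamma_B and
#' the interface Gamma_M, adventitia between Gamma_M and the outer boundary
#' Gamma_A), bounded above and below by the artificial cuts Gamma_0 at
#' y = y1, y2. The three free boundaries are cosine bulge profiles
#' `x = a * cos(pi y)/2 + b`; the default constants give a nested,
#' positive-width wall whose bulge apex sits at y = 0. The strips are meshed
#' with a structured, boundary-fitted triangulation whose media and
#' adventitia parts match node-for-node along Gamma_M.
#'
#' @name wall_geometry
NULL

.default_profile <- function() {
  list(aA = 0.7, bA = 0.3, aM = 0.55, bM = 0.2, aB = 0.5, bB = 0)
}

.profile_curves <- function(profile) {
  list(
    xB = function(y) profile$aB * cos(pi * y) / 2 + profile$bB,
    xM = function(y) profile$aM * cos(pi * y) / 2 + profile$bM,
    xA = function(y) profile$aA * cos(pi * y) / 2 + profile$bA
  )
}

#' Build the initial two-layer wall geometry
#'
#' Constructs the cosine bulge profiles on `y in [y1, y2]`, scales the
#' section uniformly so the measured initial lumen diameter equals `R0`
#' (profile units place the unscaled bulge diameter at 2, so the scale
#' factor is `R0/2`), and meshes the two strips with `ny` rows and
#' `n_med`/`n_adv` through-thickness layers, matched along the interface.
#'
#' @param R0 initial bulge diameter (cm).
#' @param ny number of element rows along y.
#' @param n_med,n_adv through-thickness element layers in media/adventitia.
#' @param profile list of profile constants `aA, bA, aM, bM, aB, bB`.
#' @param ybounds cut positions `c(y1, y2)` in profile units.
#' @param x_axis vessel centerline in profile units; the default -0.75
#'   makes the unscaled bulge diameter exactly 2.
#' @return a `wall_geometry` object: reference (`ref`) and current
#'   (`coords`) node coordinates, triangles (`tri`) with subdomain labels,
#'   boundary node chains, media/adventitia index maps for the two-sided
#'   species fields, and periodic identification of the two cut rows.
#' @examples
#' g <- build_initial_geometry(R0 = 2, ny = 8, n_med = 2, n_adv = 1)
#' measure_diameter(g)  # 2
#' @export
build_initial_geometry <- function(R0 = 2, ny = 32, n_med = 4, n_adv = 2,
                                   profile = .default_profile(),
                                   ybounds = c(-1, 1), x_axis = -0.75) {
  stopifnot(R0 > 0, ny >= 2, n_med >= 1, n_adv >= 1,
            ybounds[1] < ybounds[2])
  cv <- .profile_curves(profile)
  yy <- seq(ybounds[1], ybounds[2], length.out = 513)
  if (!all(cv$xB(yy) < cv$xM(yy)) || !all(cv$xM(yy) < cv$xA(yy))) {
    stop("profile curves are not nested (Gamma_B < Gamma_M < Gamma_A ",
         "must hold for all y)", call. = FALSE)
  }
  if (!all(cv$xB(yy) > x_axis)) {
    stop("centerline x_axis must lie left of Gamma_B", call. = FALSE)
  }
  s <- R0 / 2
  nrow_ <- ny + 1
  ncol_ <- n_med + n_adv + 1
  yrow <- seq(ybounds[1], ybounds[2], length.out = nrow_)
  node_row <- rep(seq_len(nrow_), each = ncol_)
  node_col <- rep(seq_len(ncol_), times = nrow_)
  xB <- cv$xB(yrow); xM <- cv$xM(yrow); xA <- cv$xA(yrow)
  xcoord <- numeric(nrow_ * ncol_)
  for (j in seq_len(nrow_)) {
    xm <- xB[j] + (xM[j] - xB[j]) * seq(0, 1, length.out = n_med + 1)
    xa <- xM[j] + (xA[j] - xM[j]) * seq(0, 1, length.out = n_adv + 1)
    xcoord[(j - 1) * ncol_ + seq_len(ncol_)] <- c(xm, xa[-1])
  }
  ref <- cbind(x = xcoord * s, y = rep(yrow, each = ncol_) * s)
  idx <- function(j, i) (j - 1) * ncol_ + i   # row j, column i
  # two triangles per quad, consistent positive orientation
  tri <- matrix(0L, nrow = 2 * ny * (ncol_ - 1), ncol = 3)
  sub <- character(nrow(tri))
  e <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(ncol_ - 1)) {
      n00 <- idx(j, i); n10 <- idx(j, i + 1)
      n01 <- idx(j + 1, i); n11 <- idx(j + 1, i + 1)
      lab <- if (i <= n_med) "media" else "adventitia"
      tri[e + 1L, ] <- c(n00, n10, n11)
      tri[e + 2L, ] <- c(n00, n11, n01)
      sub[e + 1L] <- lab; sub[e + 2L] <- lab
      e <- e + 2L
    }
  }
  gammaB_nodes <- idx(seq_len(nrow_), 1L)
  gammaM_nodes <- idx(seq_len(nrow_), n_med + 1L)
  gammaA_nodes <- idx(seq_len(nrow_), ncol_)
  gamma0_nodes <- c(idx(1L, seq_len(ncol_)), idx(nrow_, seq_len(ncol_)))
  # two-sided species index sets (interface nodes belong to both)
  med_nodes <- which(node_col <= n_med + 1L)
  adv_nodes <- which(node_col >= n_med + 1L)
  g2med <- rep(NA_integer_, nrow(ref)); g2med[med_nodes] <- seq_along(med_nodes)
  g2adv <- rep(NA_integer_, nrow(ref)); g2adv[adv_nodes] <- seq_along(adv_nodes)
  # periodic identification: the top cut row is the bottom cut row
  pmap <- seq_len(nrow(ref))
  pmap[idx(nrow_, seq_len(ncol_))] <- idx(1L, seq_len(ncol_))
  geom <- structure(list(
    ref = ref, coords = ref, tri = tri, sub = sub,
    ny = ny, n_med = n_med, n_adv = n_adv, ncol = ncol_,
    node_row = node_row, node_col = node_col,
    gammaB_nodes = gammaB_nodes, gammaM_nodes = gammaM_nodes,
    gammaA_nodes = gammaA_nodes, gamma0_nodes = gamma0_nodes,
    med_nodes = med_nodes, adv_nodes = adv_nodes,
    g2med = g2med, g2adv = g2adv, pmap = pmap,
    scale = s, x_axis = x_axis * s, R0 = R0,
    profile = profile, ybounds = ybounds
  ), class = "wall_geometry")
  bad <- which(.tri_areas(geom$tri, geom$ref) <= 0)
  if (length(bad)) {
    stop("mesh generation produced inverted element(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  # cache blood-side boundary edge data (adjacency, outward normals)
  geom$bnd_gammaB <- .boundary_edges(geom, gammaB_nodes)
  geom
}

#' @export
print.wall_geometry <- function(x, ...) {
  cat("<wall_geometry> ", nrow(x$ref), " nodes, ", nrow(x$tri),
      " triangles (", sum(x$sub == "media"), " media / ",
      sum(x$sub == "adventitia"), " adventitia), diameter ",
      signif(measure_diameter(x), 6), " cm\n", sep = "")
  invisible(x)
}

.tri_areas <- function(tri, coords) {
  x1 <- coords[tri[, 1], 1]; y1 <- coords[tri[, 1], 2]
  x2 <- coords[tri[, 2], 1]; y2 <- coords[tri[, 2], 2]
  x3 <- coords[tri[, 3], 1]; y3 <- coords[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# P1 element geometry: signed areas and hat-function gradients.
# Returns list(area, gx, gy) with gx/gy m x 3 matrices.
.p1_geometry <- function(tri, coords) {
  x1 <- coords[tri[, 1], 1]; y1 <- coords[tri[, 1], 2]
  x2 <- coords[tri[, 2], 1]; y2 <- coords[tri[, 2], 2]
  x3 <- coords[tri[, 3], 1]; y3 <- coords[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / a2
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / a2
  list(area = a2 / 2, gx = gx, gy = gy)
}

#' Move the mesh by the flow map
#'
#' Sets the current configuration to `reference + u` and re-checks element
#' validity. Displacement must vanish on the clamped cuts Gamma_0.
#'
#' @param geom a `wall_geometry`.
#' @param u n x 2 nodal displacement on the reference mesh (cm).
#' @param enforce_clamp check the Gamma_0 clamp (disable for free test
#'   meshes).
#' @return the geometry with updated `coords`.
#' @export
move_mesh <- function(geom, u, enforce_clamp = TRUE) {
  u <- as.matrix(u)
  stopifnot(nrow(u) == nrow(geom$ref), ncol(u) == 2)
  if (enforce_clamp && any(abs(u[geom$gamma0_nodes, ]) > 1e-12)) {
    stop("displacement must vanish on the clamped cuts Gamma_0",
         call. = FALSE)
  }
  geom$coords <- geom$ref + u
  areas <- .tri_areas(geom$tri, geom$coords)
  bad <- which(areas <= 0)
  if (length(bad)) {
    stop("element inversion after mesh move (element ", bad[1], ")",
         call. = FALSE)
  }
  geom
}

#' Measure the aneurysm bulge diameter
#'
#' Twice the maximal horizontal distance from the vessel centerline to the
#' current blood-side boundary Gamma_B. Deterministic in the nodal
#' positions; reduces to the lumen diameter for the symmetric reference
#' bulge.
#'
#' @param geom a `wall_geometry`.
#' @return diameter in cm.
#' @export
measure_diameter <- function(geom) {
  2 * max(geom$coords[geom$gammaB_nodes, 1] - geom$x_axis)
}

#' Discrete mean curvature of a polyline
#'
#' Signed curvature per node from the circumscribed circle through each
#' consecutive node triple (exact for nodes on a circle); endpoints copy the
#' adjacent interior value. Positive curvature corresponds to a
#' counter-clockwise-turning polyline.
#'
#' @param poly k x 2 matrix of node coordinates (k >= 3).
#' @param closed treat the polyline as closed.
#' @return numeric vector of curvatures (cm^-1).
#' @export
discrete_mean_curvature <- function(poly, closed = FALSE) {
  poly <- as.matrix(poly)
  k <- nrow(poly)
  stopifnot(k >= 3)
  seg <- diff(poly)
  if (any(sqrt(rowSums(seg^2)) == 0)) {
    stop("duplicate consecutive nodes in polyline", call. = FALSE)
  }
  tri_k <- function(a, b, c) {
    ab <- b - a; bc <- c - b; ac <- c - a
    cross <- ab[1] * ac[2] - ab[2] * ac[1]
    den <- sqrt(sum(ab^2) * sum(bc^2) * sum(ac^2))
    if (den == 0) 0 else 2 * cross / den
  }
  kap <- numeric(k)
  for (i in 2:(k - 1)) kap[i] <- tri_k(poly[i - 1, ], poly[i, ], poly[i + 1, ])
  if (closed) {
    kap[1] <- tri_k(poly[k - 1, ], poly[1, ], poly[2, ])
    kap[k] <- kap[1]
  } else {
    kap[1] <- kap[2]
    kap[k] <- kap[k - 1]
  }
  kap
}

#' Surface-to-volume ratios of the reference geometry
#'
#' Boundary length over layer area for the three boundaries, as used by the
#' well-mixed compartment reduction.
#'
#' @param geom a `wall_geometry`.
#' @return list `B`, `M_media`, `M_adv`, `A` (cm^-1).
#' @export
geometry_ratios <- function(geom) {
  len <- function(nodes) {
    p <- geom$ref[nodes, , drop = FALSE]
    sum(sqrt(rowSums(diff(p)^2)))
  }
  areas <- .tri_areas(geom$tri, geom$ref)
  a_med <- sum(areas[geom$sub == "media"])
  a_adv <- sum(areas[geom$sub == "adventitia"])
  lM <- len(geom$gammaM_nodes)
  list(B = len(geom$gammaB_nodes) / a_med,
       M_media = lM / a_med,
       M_adv = lM / a_adv,
       A = len(geom$gammaA_nodes) / a_adv)
}

#' Write a legacy-VTK snapshot of the current mesh
#'
#' ASCII legacy VTK (unstructured grid) with subdomain id as cell data
#' (1 = media, 2 = adventitia) and any supplied nodal fields as point data.
#'
#' @param geom a `wall_geometry`.
#' @param path output file path (.vtk).
#' @param point_data named list of numeric vectors (length = node count) or
#'   n x 2 matrices (written as vectors).
#' @return invisibly, `path`.
#' @export
write_vtk_snapshot <- function(geom, path, point_data = list()) {
  n <- nrow(geom$coords); m <- nrow(geom$tri)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("aortawall snapshot")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n, " double")
  writeLines(paste(geom$coords[, 1], geom$coords[, 2], 0), con)
  wl("CELLS ", m, " ", 4 * m)
  writeLines(paste(3, geom$tri[, 1] - 1, geom$tri[, 2] - 1,
                   geom$tri[, 3] - 1), con)
  wl("CELL_TYPES ", m)
  writeLines(as.character(rep(5L, m)), con)
  wl("CELL_DATA ", m)
  wl("SCALARS subdomain int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(ifelse(geom$sub == "media", 1L, 2L)), con)
  if (length(point_data)) {
    wl("POINT_DATA ", n)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        wl("VECTORS ", nm, " double")
        writeLines(paste(v[, 1], v[, 2], 0), con)
      } else {
        wl("SCALARS ", nm, " double 1")
        wl("LOOKUP_TABLE default")
        writeLines(as.character(v), con)
      }
    }
  }
  invisible(path)
}
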