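# Synthetic sagittal-section geometry.
#
# The mesh is an idealized parametric stand-in for an atlas-derived sagittal
# mouse-brain section: a dome-capped brain domain whose local depth tapers
# towards the anterior/posterior poles, partitioned into the published brain
# regions by a fractional (u, v) tile layout, and enclosed by a conforming
# 1.5 mm skull shell extruded outward around the whole brain boundary loop
# (a closed cranial ring; the dorsal shell the impactor strikes is part of
# it).  Coordinates: x = posterior(+)/anterior(-) in mm, y = ventral depth
# (+, increasing into the brain) in mm, origin at the impact point on the
# outer skull surface.

#' Default fractional region layout
#'
#' Tiling of the brain-local unit square (u: anterior->posterior, v: dorsal
#' ->ventral depth fraction).  A region may own several tiles (medulla does).
#' The `midbrain` tile hosts the substantia-nigra monitor and is assigned
#' thalamus material parameters.
#' @export
default_region_layout <- function() {
  data.frame(
    region = c("cortex", "hippocampus", "thalamus", "cerebellum",
               "medulla", "midbrain", "pons", "medulla"),
    u0 = c(0, 0.00, 0.30, 0.65, 0.00, 0.30, 0.65, 0),
    u1 = c(1, 0.30, 0.65, 1.00, 0.30, 0.65, 1.00, 1),
    v0 = c(0, 0.25, 0.25, 0.25, 0.55, 0.55, 0.55, 0.85),
    v1 = c(0.25, 0.55, 0.55, 0.55, 0.85, 0.85, 0.85, 1.00),
    stringsAsFactors = FALSE)
}

#' Geometry specification for the synthetic sagittal section
#'
#' @param brain_width anterior-posterior extent of the brain tissue, mm.
#' @param brain_height maximal brain tissue depth (at the impact column), mm.
#' @param skull_thickness skull shell thickness, mm (default 1.5).
#' @param dome_rise dorsal-surface rise from the impact point to the lateral
#'   poles, mm (gentle cranial dome curvature).
#' @param target_element_count requested total quad count; the generated mesh
#'   is within +/-25% of it.
#' @param region_layout fractional tile layout, see [default_region_layout()].
#' @param impactor_standoff initial gap between impactor tip and skull, mm
#'   (default 0.9).
#' @param seed integer seed for the optional boundary jitter.
#' @param jitter interior-node jitter amplitude as a fraction of local element
#'   size (default 0 = regular grid).
#' @return object of class `geometry_spec`.
#' @export
geometry_spec <- function(brain_width = 15, brain_height = 9.5,
                          skull_thickness = 1.5, dome_rise = 0.5,
                          target_element_count = 5000,
                          region_layout = default_region_layout(),
                          impactor_standoff = 0.9, seed = 1L, jitter = 0) {
  spec <- structure(list(brain_width = brain_width, brain_height = brain_height,
                         skull_thickness = skull_thickness,
                         dome_rise = dome_rise,
                         target_element_count = target_element_count,
                         region_layout = region_layout,
                         impactor_standoff = impactor_standoff,
                         seed = as.integer(seed), jitter = jitter),
                    class = "geometry_spec")
  validate_geometry_spec(spec)
  spec
}

validate_geometry_spec <- function(spec) {
  if (!is.numeric(spec$skull_thickness) || spec$skull_thickness <= 0)
    stop("invalid geometry spec: skull_thickness must be > 0")
  if (spec$brain_width <= 0)
    stop("invalid geometry spec: brain_width must be > 0")
  if (spec$brain_height <= 0)
    stop("invalid geometry spec: brain_height must be > 0")
  if (spec$impactor_standoff < 0)
    stop("invalid geometry spec: impactor_standoff must be >= 0")
  if (spec$target_element_count < 8)
    stop("invalid geometry spec: target_element_count too small")
  lay <- spec$region_layout
  if (is.null(lay) || nrow(lay) == 0)
    stop("invalid geometry spec: region_layout is empty")
  need <- c("region", "u0", "u1", "v0", "v1")
  if (!all(need %in% names(lay)))
    stop("invalid geometry spec: region_layout lacks columns ",
         paste(setdiff(need, names(lay)), collapse = ", "))
  fr <- unlist(lay[, c("u0", "u1", "v0", "v1")])
  if (any(fr < 0 | fr > 1))
    stop("invalid geometry spec: region_layout fractions must lie in [0, 1]")
  if (any(lay$u1 <= lay$u0) || any(lay$v1 <= lay$v0))
    stop("invalid geometry spec: region_layout has degenerate tiles")
  # tiling check: total area 1, pairwise overlaps empty
  area <- sum((lay$u1 - lay$u0) * (lay$v1 - lay$v0))
  if (abs(area - 1) > 1e-9)
    stop(sprintf("invalid geometry spec: region_layout covers area %.4f, not 1",
                 area))
  n <- nrow(lay)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      du <- min(lay$u1[i], lay$u1[j]) - max(lay$u0[i], lay$u0[j])
      dv <- min(lay$v1[i], lay$v1[j]) - max(lay$v0[i], lay$v0[j])
      if (du > 1e-9 && dv > 1e-9)
        stop(sprintf("invalid geometry spec: region_layout tiles %d and %d overlap",
                     i, j))
    }
  }
  invisible(spec)
}

# local brain depth profile and dorsal brain surface (mm); poles stay blunt
# (55% of the central depth) so the section has no thin anterior/posterior
# wedges, and the ventral outline tapers inward with depth to avoid sharp
# corners at the poles
brain_depth_profile <- function(spec, x) {
  spec$brain_height * (0.55 + 0.45 * (1 - (2 * x / spec$brain_width)^4))
}
brain_dorsal_surface <- function(spec, x) {
  spec$skull_thickness + spec$dome_rise * (2 * x / spec$brain_width)^2
}
VENTRAL_TAPER <- 0.1

# pick grid resolution: prefer nx, ny that are multiples of 20 so the default
# fractional layout breaks (x/20) land exactly on element rows/columns, which
# makes labeled region areas refinement-invariant.
choose_grid <- function(spec) {
  W <- spec$brain_width
  xg <- seq(-W / 2, W / 2, length.out = 201)
  meanH <- mean(brain_depth_profile(spec, xg))
  cand <- sort(unique(c(seq(4, 400, by = 2), seq(20, 400, by = 20))))
  best <- NULL
  for (nx in cand) {
    dx <- W / nx
    nyr <- meanH / dx
    ny <- if (nx %% 20 == 0 && nyr >= 10) max(20, 20 * round(nyr / 20))
          else max(4, round(nyr))
    nsk <- max(2, round(spec$skull_thickness / dx))
    cnt <- nx * ny + 2 * (nx + ny) * nsk
    score <- abs(cnt - spec$target_element_count) +
      if (nx %% 20 == 0 && ny %% 20 == 0) 0 else 0.15 * spec$target_element_count
    if (is.null(best) || score < best$score)
      best <- list(nx = nx, ny = ny, nsk = nsk, count = cnt, score = score)
  }
  best
}

#' Build the synthetic sagittal brain + skull mesh
#'
#' Generates the region-labeled conforming quadrilateral mesh: a structured
#' brain block mapped under the dome/depth profiles, with the skull shell
#' extruded outward around the closed brain boundary (so the skull-brain
#' interface shares nodes, the exact conforming equivalent of a tie
#' constraint).  Region labels are assigned by fractional tiles snapped to
#' grid lines.
#'
#' @param spec a [geometry_spec()].
#' @return object of class `regioned_mesh` with fields `nodes` (mm),
#'   `elements` (4-node connectivity, positively oriented), `region`
#'   (per-element label), `region_materials`, `boundary_sets`, `monitors`.
#' @export
build_sagittal_domain <- function(spec) {
  validate_geometry_spec(spec)
  W <- spec$brain_width
  g <- choose_grid(spec)
  nx <- g$nx; ny <- g$ny; nsk <- g$nsk
  if (abs(g$count - spec$target_element_count) > 0.25 * spec$target_element_count)
    warning(sprintf("generated element count %d misses target %d by more than 25%%",
                    g$count, spec$target_element_count))

  xs <- seq(-W / 2, W / 2, length.out = nx + 1)
  ytop <- brain_dorsal_surface(spec, xs)
  H <- brain_depth_profile(spec, xs)

  # brain grid nodes, id(i,j) = j*(nx+1) + i + 1 (i = 0..nx, j = 0..ny)
  nb <- (nx + 1) * (ny + 1)
  nodes <- matrix(0, nb, 2)
  for (j in 0:ny) {
    v <- j / ny
    idx <- j * (nx + 1) + seq_len(nx + 1)
    nodes[idx, 1] <- xs * (1 - VENTRAL_TAPER * v^2)
    nodes[idx, 2] <- ytop + v * H
  }
  gid <- function(i, j) j * (nx + 1) + i + 1

  if (spec$jitter > 0) {
    set.seed(spec$seed)
    dx <- W / nx
    for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
      id <- gid(i, j)
      nodes[id, ] <- nodes[id, ] +
        stats::runif(2, -spec$jitter * dx, spec$jitter * dx)
    }
  }

  # brain elements + labels
  lay <- spec$region_layout
  iu0 <- round(lay$u0 * nx); iu1 <- round(lay$u1 * nx)
  jv0 <- round(lay$v0 * ny); jv1 <- round(lay$v1 * ny)
  eb <- nx * ny
  elems <- matrix(0L, eb, 4)
  region <- character(eb)
  k <- 0
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    k <- k + 1
    elems[k, ] <- c(gid(i, j), gid(i + 1, j), gid(i + 1, j + 1), gid(i, j + 1))
    hit <- which(i >= iu0 & i < iu1 & j >= jv0 & j < jv1)
    if (length(hit) == 0)
      stop(sprintf("region layout leaves element (%d,%d) unlabeled", i, j))
    region[k] <- lay$region[hit[1]]
  }

  # closed boundary loop of the brain block (top, right, bottom, left)
  loop <- c(gid(0:nx, 0),
            gid(nx, 1:ny),
            gid((nx - 1):0, ny),
            gid(0, (ny - 1):1))
  nloop <- length(loop)
  lp <- nodes[loop, , drop = FALSE]
  nxt <- c(2:nloop, 1)
  prv <- c(nloop, 1:(nloop - 1))
  segn <- function(a, b) { # outward normal of segment a->b
    t <- b - a
    n <- c(t[2], -t[1])
    n / sqrt(sum(n^2))
  }
  vnorm <- matrix(0, nloop, 2)
  for (kk in seq_len(nloop)) {
    n1 <- segn(lp[prv[kk], ], lp[kk, ])
    n2 <- segn(lp[kk, ], lp[nxt[kk], ])
    n <- n1 + n2
    vnorm[kk, ] <- n / sqrt(sum(n^2))
  }

  # skull ring: nsk layers extruded outward along vertex normals
  ring_ids <- matrix(0L, nsk + 1, nloop)
  ring_ids[1, ] <- loop
  rn <- nb
  ring_nodes <- matrix(0, nsk * nloop, 2)
  for (l in 1:nsk) {
    off <- spec$skull_thickness * l / nsk
    for (kk in seq_len(nloop)) {
      rn <- rn + 1
      ring_nodes[rn - nb, ] <- lp[kk, ] + off * vnorm[kk, ]
      ring_ids[l + 1, kk] <- rn
    }
  }
  nodes <- rbind(nodes, ring_nodes)

  ring_elems <- matrix(0L, nsk * nloop, 4)
  k <- 0
  for (l in 1:nsk) for (kk in seq_len(nloop)) {
    k <- k + 1
    ring_elems[k, ] <- c(ring_ids[l + 1, kk], ring_ids[l + 1, nxt[kk]],
                         ring_ids[l, nxt[kk]], ring_ids[l, kk])
  }
  elems <- rbind(elems, ring_elems)
  storage.mode(elems) <- "integer"
  region <- c(region, rep("skull", nsk * nloop))

  outer_loop <- ring_ids[nsk + 1, ]
  outer_segs <- cbind(outer_loop, outer_loop[nxt])
  mesh <- structure(
    list(nodes = nodes, elements = elems, region = region,
         region_materials = c(cortex = "Cortex", thalamus = "Thalamus",
                              cerebellum = "Cerebellum",
                              hippocampus = "Hippocampus", medulla = "Medulla",
                              pons = "Pons", midbrain = "Thalamus",
                              skull = "Skull"),
         boundary_sets = list(
           skull_outer = list(nodes = outer_loop, segments = outer_segs),
           skull_brain_interface = list(nodes = loop,
                                        segments = cbind(loop, loop[nxt]))),
         monitors = NULL, spec = spec,
         grid = list(nx = nx, ny = ny, nsk = nsk)),
    class = "regioned_mesh")
  mesh$monitors <- tryCatch(place_monitors(mesh), error = function(e) NULL)
  mesh
}

#' @export
print.regioned_mesh <- function(x, ...) {
  cat(sprintf("<regioned_mesh> %d nodes, %d quad elements, regions: %s\n",
              nrow(x$nodes), nrow(x$elements),
              paste(sort(unique(x$region)), collapse = ", ")))
  if (!is.null(x$monitors))
    cat(sprintf("  monitors: %s\n", paste(x$monitors$name, collapse = ", ")))
  invisible(x)
}

#' Labeled region areas
#'
#' @param mesh a `regioned_mesh`.
#' @return named vector of per-region areas (mm^2).
#' @export
region_areas <- function(mesh) {
  el <- mesh$elements
  x <- matrix(mesh$nodes[el, 1], nrow(el), 4)
  y <- matrix(mesh$nodes[el, 2], nrow(el), 4)
  a <- abs(0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
                  (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
                  (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
                  (x[, 4] * y[, 1] - x[, 1] * y[, 4])))
  tapply(a, mesh$region, sum)
}

#' Minimum corner Jacobian per element
#'
#' Positive values for all elements certify a valid (non-inverted,
#' non-degenerate) quad mesh.
#' @param mesh a `regioned_mesh`.
#' @export
mesh_jacobian_min <- function(mesh) {
  fem_jacobian_min(mesh$nodes, mesh$elements)
}

# invert the bilinear map of element `e` at physical point p (Newton);
# returns c(xi, eta) or NULL if outside
invert_bilinear <- function(mesh, e, p, tol = 1e-10) {
  xn <- mesh$nodes[mesh$elements[e, ], 1]
  yn <- mesh$nodes[mesh$elements[e, ], 2]
  xi <- 0; eta <- 0
  for (it in 1:25) {
    N <- 0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
                  (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
    dNdxi <- 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta))
    dNdeta <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
    r <- c(sum(N * xn) - p[1], sum(N * yn) - p[2])
    if (max(abs(r)) < tol * max(1, max(abs(xn)), max(abs(yn)))) break
    J <- matrix(c(sum(dNdxi * xn), sum(dNdeta * xn),
                  sum(dNdxi * yn), sum(dNdeta * yn)), 2, 2, byrow = TRUE)
    d <- solve(J, r)
    xi <- xi - d[1]; eta <- eta - d[2]
    if (max(abs(c(xi, eta))) > 3) return(NULL)
  }
  if (max(abs(c(xi, eta))) <= 1 + 1e-8) c(xi, eta) else NULL
}

# locate the element containing p; returns list(elem, xi, eta) or NULL
locate_point <- function(mesh, p) {
  el <- mesh$elements
  x <- matrix(mesh$nodes[el, 1], nrow(el), 4)
  y <- matrix(mesh$nodes[el, 2], nrow(el), 4)
  tol <- 1e-9 * max(abs(mesh$nodes))
  cand <- which(p[1] >= apply(x, 1, min) - tol & p[1] <= apply(x, 1, max) + tol &
                p[2] >= apply(y, 1, min) - tol & p[2] <= apply(y, 1, max) + tol)
  for (e in cand) {
    loc <- invert_bilinear(mesh, e, p)
    if (!is.null(loc)) return(list(elem = e, xi = loc[1], eta = loc[2]))
  }
  NULL
}

#' Place the five monitoring points
#'
#' Cortex, thalamus, and substantia nigra monitors sit 2.4, 4.1, and 8.2 mm
#' vertically below the impact point; cerebellum and brainstem monitors sit
#' 4.7 mm posterior to those, at 4.1 and 8.2 mm depth.  Each is snapped to
#' its containing element with isoparametric local coordinates.
#'
#' @param mesh a `regioned_mesh`.
#' @param impact_point 2D point on the outer skull surface, mm.
#' @return data.frame with columns `name`, `x`, `y`, `elem`, `xi`, `eta`,
#'   `region` (host element's region label).
#' @export
place_monitors <- function(mesh, impact_point = c(0, 0)) {
  off <- rbind(cortex = c(0, 2.4), thalamus = c(0, 4.1),
               substantia_nigra = c(0, 8.2), cerebellum = c(4.7, 4.1),
               brainstem = c(4.7, 8.2))
  out <- vector("list", nrow(off))
  for (i in seq_len(nrow(off))) {
    p <- impact_point + off[i, ]
    loc <- locate_point(mesh, p)
    if (is.null(loc) || mesh$region[loc$elem] == "skull")
      stop(sprintf("monitor '%s' at (%.2f, %.2f) mm falls outside the brain domain",
                   rownames(off)[i], p[1], p[2]))
    out[[i]] <- data.frame(name = rownames(off)[i], x = p[1], y = p[2],
                           elem = loc$elem, xi = loc$xi, eta = loc$eta,
                           region = mesh$region[loc$elem],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Structured rectangular block mesh
#'
#' Utility mesh for single-element and benchmark problems (bars, oscillators,
#' bounce blocks).
#'
#' @param nx,ny element counts.
#' @param xlim,ylim extents in mm.
#' @param region region label for all elements.
#' @param material material name mapped to `region`.
#' @return a `regioned_mesh`.
#' @export
make_block_mesh <- function(nx, ny, xlim = c(0, 1), ylim = c(0, 1),
                            region = "block", material = "Cortex") {
  xs <- seq(xlim[1], xlim[2], length.out = nx + 1)
  ys <- seq(ylim[1], ylim[2], length.out = ny + 1)
  nodes <- cbind(rep(xs, ny + 1), rep(ys, each = nx + 1))
  gid <- function(i, j) j * (nx + 1) + i + 1
  elems <- matrix(0L, nx * ny, 4)
  k <- 0
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    k <- k + 1
    elems[k, ] <- c(gid(i, j), gid(i + 1, j), gid(i + 1, j + 1), gid(i, j + 1))
  }
  storage.mode(elems) <- "integer"
  rm_map <- stats::setNames(material, region)
  structure(list(nodes = nodes, elements = elems,
                 region = rep(region, nx * ny), region_materials = rm_map,
                 boundary_sets = list(), monitors = NULL, spec = NULL,
                 grid = list(nx = nx, ny = ny, nsk = 0)),
            class = "regioned_mesh")
}

#' Impactor specification
#'
#' Dimensions are configurable surrogates (the published source documents the
#' materials but not printable dimensions): a brass body above a slightly
#' concave nylon tip.  In rigid mode the impactor moves as a single vertical
#' translational degree of freedom with `mass_per_thickness`; the default
#' 13.75 kg/m is the 220 g drop-weight mass scaled by the 16 mm section
#' thickness of the extruded 3D model.
#'
#' @param tip_radius tip half-width, mm.
#' @param tip_concavity central recess of the concave tip face, mm.
#' @param tip_height nylon tip height, mm.
#' @param body_width,body_height brass body dimensions, mm.
#' @param tip_material,body_material material names (must exist in the
#'   built-in table or in `materials`).
#' @param rigid logical; rigid single-DOF mode (the supported dynamic mode).
#' @param mass_per_thickness effective rigid mass per metre thickness, kg/m.
#' @param n_face_segments number of contact segments across the tip face.
#' @export
impactor_spec <- function(tip_radius = 2, tip_concavity = 0.2, tip_height = 2,
                          body_width = 6, body_height = 10,
                          tip_material = "Nylon", body_material = "Brass",
                          rigid = TRUE, mass_per_thickness = 13.75,
                          n_face_segments = 8) {
  structure(list(tip_radius = tip_radius, tip_concavity = tip_concavity,
                 tip_height = tip_height, body_width = body_width,
                 body_height = body_height, tip_material = tip_material,
                 body_material = body_material, rigid = rigid,
                 mass_per_thickness = mass_per_thickness,
                 n_face_segments = n_face_segments),
            class = "impactor_spec")
}

#' Build the impactor mesh
#'
#' Builds the impactor in local coordinates (y = 0 at the tip face edges,
#' negative y upward into the body), reports its geometric mass per unit
#' thickness (density x area), and attaches the tip-face contact segments.
#'
#' @param spec an [impactor_spec()].
#' @param materials material table, default [builtin_material_table()].
#' @return a `regioned_mesh` with attributes `rigid`, `mass_per_thickness`
#'   (effective rigid mass), `mass_geometric` (density x area, kg/m), and
#'   `face_segments` (contact polyline, mm).
#' @export
build_impactor <- function(spec = impactor_spec(),
                           materials = builtin_material_table()) {
  for (mn in c(spec$tip_material, spec$body_material))
    if (!mn %in% names(materials))
      stop(sprintf("unknown material '%s' in impactor spec", mn))
  r <- spec$tip_radius; cc <- spec$tip_concavity
  face_y <- function(x) -cc * (1 - (x / r)^2)  # edges at 0, center recessed
  ntx <- max(4, 2 * round(r)); nty <- max(2, round(spec$tip_height))
  xs <- seq(-r, r, length.out = ntx + 1)
  nodes <- NULL; elems <- NULL; region <- character(0)
  # tip block, j = 0 at the top of the tip (most negative y), j = nty at face
  gid <- function(i, j, off, nx) off + j * (nx + 1) + i + 1
  tipn <- matrix(0, (ntx + 1) * (nty + 1), 2)
  for (j in 0:nty) {
    v <- j / nty  # 0 at top, 1 at face
    idx <- j * (ntx + 1) + seq_len(ntx + 1)
    tipn[idx, 1] <- xs
    tipn[idx, 2] <- (1 - v) * (-spec$tip_height) + v * face_y(xs)
  }
  tipe <- matrix(0L, ntx * nty, 4)
  k <- 0
  for (j in 0:(nty - 1)) for (i in 0:(ntx - 1)) {
    k <- k + 1
    tipe[k, ] <- c(gid(i, j, 0, ntx), gid(i + 1, j, 0, ntx),
                   gid(i + 1, j + 1, 0, ntx), gid(i, j + 1, 0, ntx))
  }
  nodes <- tipn; elems <- tipe
  region <- rep("impactor_tip", nrow(tipe))
  # body block above the tip (separate nodes; rigid-mode surrogate)
  bw <- spec$body_width; bh <- spec$body_height
  nbx <- max(4, 2 * round(bw / 2)); nby <- max(4, round(bh))
  bxs <- seq(-bw / 2, bw / 2, length.out = nbx + 1)
  bys <- seq(-spec$tip_height - bh, -spec$tip_height, length.out = nby + 1)
  off <- nrow(nodes)
  bn <- cbind(rep(bxs, nby + 1), rep(bys, each = nbx + 1))
  be <- matrix(0L, nbx * nby, 4)
  k <- 0
  for (j in 0:(nby - 1)) for (i in 0:(nbx - 1)) {
    k <- k + 1
    be[k, ] <- c(gid(i, j, off, nbx), gid(i + 1, j, off, nbx),
                 gid(i + 1, j + 1, off, nbx), gid(i, j + 1, off, nbx))
  }
  nodes <- rbind(nodes, bn); elems <- rbind(elems, be)
  storage.mode(elems) <- "integer"
  region <- c(region, rep("impactor_body", nrow(be)))

  mesh <- structure(
    list(nodes = nodes, elements = elems, region = region,
         region_materials = c(impactor_tip = spec$tip_material,
                              impactor_body = spec$body_material),
         boundary_sets = list(), monitors = NULL, spec = spec,
         grid = NULL),
    class = "regioned_mesh")
  ar <- region_areas(mesh) * 1e-6  # m^2 per metre thickness
  dens <- vapply(mesh$region_materials[names(ar)],
                 function(mn) materials[[mn]]$density, numeric(1))
  mass_geo <- sum(ar * dens)
  nseg <- spec$n_face_segments
  fx <- seq(-r, r, length.out = nseg + 1)
  fy <- face_y(fx)
  attr(mesh, "rigid") <- spec$rigid
  attr(mesh, "mass_geometric") <- mass_geo
  attr(mesh, "mass_per_thickness") <-
    if (spec$rigid) spec$mass_per_thickness else mass_geo
  attr(mesh, "face_segments") <- cbind(fx[-(nseg + 1)], fy[-(nseg + 1)],
                                       fx[-1], fy[-1])
  mesh
}
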