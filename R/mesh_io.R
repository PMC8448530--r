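# Legacy ASCII VTK unstructured-grid I/O for regioned quad meshes and field
# snapshots.  Region labels (strings) have no native VTK cell-array type, so
# the label<->id dictionary is carried in the VTK title line:
#   neuroimpact|regions=a,b,c|mats=X,Y,Z
# and cells carry an integer `region_id` array.

#' Write a regioned mesh as a legacy ASCII VTK unstructured grid
#'
#' @param mesh a `regioned_mesh` (coordinates in mm).
#' @param path output file path.
#' @param cell_data optional named list of extra per-element numeric arrays.
#' @param point_data optional named list of per-node numeric arrays (vectors
#'   of length n, or n x 2 matrices written as 3-vectors with z = 0).
#' @export
write_mesh <- function(mesh, path, cell_data = NULL, point_data = NULL) {
  stopifnot(inherits(mesh, "regioned_mesh"))
  regs <- sort(unique(mesh$region))
  mats <- mesh$region_materials[regs]
  mats[is.na(mats)] <- ""
  rid <- match(mesh$region, regs) - 1L
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("neuroimpact|regions=%s|mats=%s", paste(regs, collapse = ","),
     paste(mats, collapse = ","))
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", nn)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  wl("CELLS %d %d", ne, 5L * ne)
  writeLines(sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L,
                     mesh$elements[, 4] - 1L), con)
  wl("CELL_TYPES %d", ne)
  writeLines(rep("9", ne), con)
  wl("CELL_DATA %d", ne)
  wl("SCALARS region_id int 1")
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%d", rid), con)
  if (!is.null(cell_data)) {
    for (nm in names(cell_data)) {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.17g", cell_data[[nm]]), con)
    }
  }
  if (!is.null(point_data)) {
    wl("POINT_DATA %d", nn)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        wl("VECTORS %s double", nm)
        writeLines(sprintf("%.17g %.17g 0", v[, 1], v[, 2]), con)
      } else {
        wl("SCALARS %s double 1", nm)
        wl("LOOKUP_TABLE default")
        writeLines(sprintf("%.17g", v), con)
      }
    }
  }
  invisible(path)
}

#' Read a regioned mesh from a legacy ASCII VTK file
#'
#' Parses files produced by [write_mesh()]; malformed input raises a parse
#' error naming the offending line.  Monitors and boundary sets are not part
#' of the format and come back empty.
#'
#' @param path VTK file path.
#' @return a `regioned_mesh`.
#' @export
read_mesh <- function(path) {
  ln <- readLines(path)
  perr <- function(i, what) stop(sprintf("VTK parse error at line %d: %s", i, what))
  find <- function(pat) {
    i <- grep(pat, ln)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  if (length(ln) < 5 || !grepl("^# vtk DataFile", ln[1]))
    perr(1, "not a legacy VTK file")
  title <- ln[2]
  regs <- character(0); mats <- character(0)
  if (grepl("regions=", title)) {
    parts <- strsplit(title, "|", fixed = TRUE)[[1]]
    rp <- grep("^regions=", parts, value = TRUE)
    mp <- grep("^mats=", parts, value = TRUE)
    if (length(rp)) regs <- strsplit(sub("^regions=", "", rp), ",")[[1]]
    if (length(mp)) mats <- strsplit(sub("^mats=", "", mp), ",")[[1]]
  }
  ip <- find("^POINTS ")
  if (is.na(ip)) perr(1, "POINTS section missing")
  nn <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  if (is.na(nn)) perr(ip, "bad POINTS count")
  pts <- ln[(ip + 1):(ip + nn)]
  co <- strsplit(trimws(pts), "\\s+")
  bad <- which(vapply(co, length, 1L) < 2)
  if (length(bad)) perr(ip + bad[1], "bad point coordinates")
  nodes <- suppressWarnings(cbind(as.numeric(vapply(co, `[`, "", 1)),
                                  as.numeric(vapply(co, `[`, "", 2))))
  if (any(is.na(nodes))) perr(ip + which(is.na(rowSums(nodes)))[1], "non-numeric coordinate")
  ic <- find("^CELLS ")
  if (is.na(ic)) perr(ip + nn, "CELLS section missing")
  ne <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  ce <- strsplit(trimws(ln[(ic + 1):(ic + ne)]), "\\s+")
  bad <- which(vapply(ce, function(z) z[1] != "4" || length(z) != 5, TRUE))
  if (length(bad)) perr(ic + bad[1], "only 4-node quad cells are supported")
  elems <- t(vapply(ce, function(z) as.integer(z[2:5]) + 1L, integer(4)))
  it <- find("^CELL_TYPES ")
  if (is.na(it)) perr(ic + ne, "CELL_TYPES section missing")
  ty <- trimws(ln[(it + 1):(it + ne)])
  if (any(ty != "9")) perr(it + which(ty != "9")[1], "cell type is not VTK_QUAD (9)")
  icd <- find("^CELL_DATA ")
  if (is.na(icd)) perr(it + ne, "CELL_DATA section with region ids missing")
  irid <- grep("^SCALARS region_id", ln)
  if (length(irid) == 0) perr(icd, "region_id cell-data array missing")
  irid <- irid[1]
  rid <- suppressWarnings(as.integer(trimws(ln[(irid + 2):(irid + 1 + ne)])))
  if (any(is.na(rid))) perr(irid + 2 + which(is.na(rid))[1] - 1, "bad region id")
  if (length(regs) == 0) regs <- paste0("region", sort(unique(rid)))
  if (any(rid + 1L > length(regs))) perr(irid, "region id exceeds region dictionary")
  region <- regs[rid + 1L]
  rm_map <- if (length(mats) == length(regs)) stats::setNames(mats, regs)
            else stats::setNames(rep(NA_character_, length(regs)), regs)
  structure(list(nodes = nodes, elements = elems, region = region,
                 region_materials = rm_map, boundary_sets = list(),
                 monitors = NULL, spec = NULL, grid = NULL),
            class = "regioned_mesh")
}

#' Export the assembled model as a solver-neutral keyword deck
#'
#' Plain-text deck (nodes, elements with region/material cards, material
#' definitions, contact surface) for cross-checking the assembled problem in
#' third-party FEM codes.
#'
#' @param mesh a `regioned_mesh`.
#' @param path output file.
#' @param materials material table.
#' @export
write_deck <- function(mesh, path, materials = builtin_material_table()) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("*HEADING")
  wl("neuroimpact keyword deck (units: mm, Pa, kg/m^3, ms)")
  wl("*NODE")
  writeLines(sprintf("%d, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  for (rg in sort(unique(mesh$region))) {
    wl("*ELEMENT, TYPE=CPE4, ELSET=%s", rg)
    idx <- which(mesh$region == rg)
    writeLines(sprintf("%d, %d, %d, %d, %d", idx, mesh$elements[idx, 1],
                       mesh$elements[idx, 2], mesh$elements[idx, 3],
                       mesh$elements[idx, 4]), con)
  }
  for (rg in sort(unique(mesh$region))) {
    mn <- unname(mesh$region_materials[rg])
    if (length(mn) != 1 || is.na(mn) || !mn %in% names(materials)) next
    m <- materials[[mn]]
    wl("*SOLID SECTION, ELSET=%s, MATERIAL=%s", rg, mn)
    wl("*MATERIAL, NAME=%s", mn)
    wl("*DENSITY")
    wl("%g", m$density)
    if (inherits(m, "prony_material")) {
      wl("*VISCOELASTIC, TIME=PRONY")
      wl("%g, 0., %g", m$g1, m$tau1)
      wl("%g, 0., %g", m$g2, m$tau2)
      wl("*SHEAR MODULUS (INSTANTANEOUS)")
      wl("%g", instantaneous_shear_modulus(m))
      wl("*EFFECTIVE POISSON RATIO")
      wl("%g", m$poisson_eff)
    } else {
      wl("*ELASTIC")
      wl("%g, %g", m$E, m$nu)
    }
  }
  invisible(path)
}
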