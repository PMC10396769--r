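#' Define a synthetic pelvis-fragment-screw geometry
#'
#' Parametric stand-in for the postoperative hemipelvis: a rectangular
#' iliac block cut by an oblique osteotomy plane (the acetabular fragment
#' below, the retained ilium above) with cylindrical screws crossing the
#' plane. Supported fixation layouts: `IS` (three oblique iliac-crest
#' screws), `TS` (two oblique screws plus one transverse screw), and the
#' five two-screw subsets `2S-a` ... `2S-e` (`2S-a`-`2S-c` drop one iliac
#' screw each, `2S-a` dropping the most medial; `2S-d`/`2S-e` pair one
#' oblique screw with the transverse screw).
#'
#' @param fixation Fixation layout code.
#' @param dims Block dimensions (x, y, z), mm.
#' @param osteotomy_point,osteotomy_normal Point and normal of the
#'   osteotomy plane, mm (fragment on the negative side).
#' @param target_edge_size Structured-mesh edge size, mm.
#' @param screw_radius Screw radius, mm (screws are smooth cylinders
#'   without thread geometry).
#' @param screw_axes Optional list overriding the layout's screw axes; each
#'   element is `list(name, entry, direction, length)`.
#' @param seed Integer seed (kept for reproducibility metadata).
#' @return A `paosim_geometry_spec` list.
#' @export
geometry_spec <- function(fixation = c("IS", "TS", "2S-a", "2S-b", "2S-c",
                                       "2S-d", "2S-e"),
                          dims = c(60, 40, 50),
                          osteotomy_point = c(30, 20, 22),
                          osteotomy_normal = c(-0.25, 0, 1),
                          target_edge_size = 4,
                          screw_radius = 3.25,
                          screw_axes = NULL,
                          seed = 1L) {
  fixation <- match.arg(fixation)
  if (target_edge_size <= 0) {
    stop_paosim("target_edge_size must be positive", "paosim_config_error")
  }
  obl <- function(name, x, y) {
    list(name = name, entry = c(x, y, dims[3]), direction = c(0, 0, -1),
         length = 44)
  }
  trans <- list(name = "screw_transverse", entry = c(dims[1], 20, 26),
                direction = c(-1, 0, 0), length = 45)
  axes <- switch(fixation,
    "IS" = list(obl("screw_medial", 15, 14), obl("screw_central", 30, 20),
                obl("screw_lateral", 45, 26)),
    "TS" = list(obl("screw_oblique1", 20, 16), obl("screw_oblique2", 40, 24),
                trans),
    "2S-a" = list(obl("screw_central", 30, 20), obl("screw_lateral", 45, 26)),
    "2S-b" = list(obl("screw_medial", 15, 14), obl("screw_lateral", 45, 26)),
    "2S-c" = list(obl("screw_medial", 15, 14), obl("screw_central", 30, 20)),
    "2S-d" = list(obl("screw_oblique1", 20, 16), trans),
    "2S-e" = list(obl("screw_oblique2", 40, 24), trans))
  if (!is.null(screw_axes)) axes <- screw_axes
  n_expect <- if (fixation %in% c("IS", "TS")) 3L else 2L
  if (is.null(screw_axes) && length(axes) != n_expect) {
    stop_paosim("layout has the wrong number of screws",
                "paosim_config_error")
  }
  structure(list(fixation = fixation, dims = as.numeric(dims),
                 osteotomy_point = as.numeric(osteotomy_point),
                 osteotomy_normal = as.numeric(osteotomy_normal) /
                   sqrt(sum(osteotomy_normal^2)),
                 target_edge_size = target_edge_size,
                 screw_radius = screw_radius,
                 screw_axes = axes, seed = as.integer(seed)),
            class = "paosim_geometry_spec")
}

plane_signed_distance <- function(pts, plane) {
  drop(sweep(pts, 2, plane$point) %*% plane$normal)
}

# distance from points to a finite axis segment
.segment_distance <- function(pts, a, d, len) {
  dn <- d / sqrt(sum(d^2))
  rel <- sweep(pts, 2, a)
  t <- pmin(pmax(drop(rel %*% dn), 0), len)
  foot <- outer(t, dn)
  sqrt(rowSums((rel - foot)^2))
}

tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE] - a
  c_ <- nodes[elements[, 3], , drop = FALSE] - a
  d <- nodes[elements[, 4], , drop = FALSE] - a
  det <- b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
    b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
    b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])
  det / 6
}

#' Element centroids of a tetrahedral mesh
#' @param mesh A `paosim_tet_mesh`.
#' @return Matrix (n_elements x 3) of centroids, mm.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
     mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
}

#' Surface nodes of a tetrahedral mesh
#'
#' Nodes lying on boundary faces (faces shared by exactly one element).
#' @param mesh A `paosim_tet_mesh`.
#' @return Integer vector of node indices.
#' @export
mesh_surface_nodes <- function(mesh) {
  el <- mesh$elements
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                 el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  bkey <- names(tab)[tab == 1]
  bfaces <- faces[key %in% bkey, , drop = FALSE]
  sort(unique(as.integer(bfaces)))
}

# structured tet4 mesh of a box [0,L1]x[0,L2]x[0,L3]
.box_tet_mesh <- function(dims, h) {
  nd <- pmax(ceiling(dims / h), 2L)
  xs <- seq(0, dims[1], length.out = nd[1] + 1)
  ys <- seq(0, dims[2], length.out = nd[2] + 1)
  zs <- seq(0, dims[3], length.out = nd[3] + 1)
  nn <- function(i, j, k) {
    (k - 1) * (nd[1] + 1) * (nd[2] + 1) + (j - 1) * (nd[1] + 1) + i
  }
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  tets <- vector("list", prod(nd))
  idx <- 0
  splits <- list(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                 c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  for (k in seq_len(nd[3])) for (j in seq_len(nd[2])) {
    for (i in seq_len(nd[1])) {
      v <- c(nn(i, j, k), nn(i + 1, j, k), nn(i + 1, j + 1, k),
             nn(i, j + 1, k), nn(i, j, k + 1), nn(i + 1, j, k + 1),
             nn(i + 1, j + 1, k + 1), nn(i, j + 1, k + 1))
      idx <- idx + 1
      tets[[idx]] <- t(vapply(splits, function(s) v[s], numeric(4)))
    }
  }
  elements <- do.call(rbind, tets)
  vol <- tet_volumes(nodes, elements)
  neg <- vol < 0
  if (any(neg)) {
    elements[neg, c(3, 4)] <- elements[neg, c(4, 3)]
  }
  list(nodes = nodes, elements = elements)
}

#' Generate the synthetic pelvis-fragment-screw tetrahedral mesh
#'
#' Builds a watertight structured tet4 mesh of the geometry defined by a
#' [geometry_spec()]: elements are labeled as acetabular fragment or
#' retained ilium by the side of the osteotomy plane, screw elements are
#' those whose centroid lies within the screw radius of a screw axis
#' (screws share nodes with the bone: bonded fixation), and surface node
#' sets mark the fixed boundary (superior/sacroiliac face), the muscle
#' coupling patches (one per functional group), the joint contact patch on
#' the fragment, and the osteotomy surface band.
#'
#' @param spec A `paosim_geometry_spec`.
#' @return A `paosim_tet_mesh`: list with `nodes` (mm), `elements`,
#'   `elsets`, `nsets`, `osteotomy_plane`, `edge_size`, `spec`.
#' @export
generate_pelvis_mesh <- function(spec) {
  stopifnot(inherits(spec, "paosim_geometry_spec"))
  h <- spec$target_edge_size
  bm <- .box_tet_mesh(spec$dims, h)
  nodes <- bm$nodes
  elements <- bm$elements
  ne <- nrow(elements)
  cen <- (nodes[elements[, 1], ] + nodes[elements[, 2], ] +
            nodes[elements[, 3], ] + nodes[elements[, 4], ]) / 4
  plane <- list(point = spec$osteotomy_point, normal = spec$osteotomy_normal)
  side <- plane_signed_distance(cen, plane)
  is_screw <- rep(FALSE, ne)
  elsets <- list()
  for (ax in spec$screw_axes) {
    d <- .segment_distance(cen, ax$entry, ax$direction, ax$length)
    sel <- which(d <= spec$screw_radius & !is_screw)
    if (length(sel) == 0) {
      stop_paosim(sprintf("screw '%s' does not intersect the mesh", ax$name),
                  "paosim_geometry_error")
    }
    sides <- side[sel]
    if (!(any(sides < 0) && any(sides > 0))) {
      stop_paosim(sprintf(
        "screw '%s' does not cross the osteotomy plane (no purchase in %s)",
        ax$name, if (any(sides < 0)) "the retained ilium" else "the fragment"),
        "paosim_geometry_error")
    }
    elsets[[ax$name]] <- sel
    is_screw[sel] <- TRUE
  }
  elsets$fragment <- which(side < 0 & !is_screw)
  elsets$ilium <- which(side >= 0 & !is_screw)
  elsets$bone <- sort(c(elsets$fragment, elsets$ilium))
  L <- spec$dims
  x <- nodes[, 1]; y <- nodes[, 2]; z <- nodes[, 3]
  tol <- 1e-8
  nsets <- list(
    fixed = which(z > L[3] - tol),
    couple_joint = which(z < tol & abs(x - L[1] / 2) <= 12 &
                           abs(y - L[2] / 2) <= 12),
    couple_abductor = which(y > L[2] - tol & z >= 0.55 * L[3] &
                              x >= 0.2 * L[1] & x <= 0.8 * L[1]),
    couple_flexor = which(x < tol & z >= 0.4 * L[3] & z <= 0.8 * L[3]),
    couple_extensor = which(x > L[1] - tol & z >= 0.4 * L[3] &
                              z <= 0.8 * L[3]),
    couple_adductor = which(y < tol & z >= 0.2 * L[3] & z <= 0.6 * L[3]),
    osteotomy = which(abs(plane_signed_distance(nodes, plane)) <= 0.51 * h)
  )
  out <- list(nodes = nodes, elements = elements, elsets = elsets,
              nsets = nsets, osteotomy_plane = plane, edge_size = h,
              spec = spec)
  class(out) <- "paosim_tet_mesh"
  out
}

#' @export
print.paosim_tet_mesh <- function(x, ...) {
  cat("Tet4 mesh:", nrow(x$nodes), "nodes,", nrow(x$elements),
      "elements\n")
  cat("Element sets:", paste(names(x$elsets), collapse = ", "), "\n")
  cat("Node sets:", paste(names(x$nsets), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.paosim_tet_mesh <- function(x, ...) {
  ne <- nrow(x$elements)
  lab <- rep("bone", ne)
  for (nm in names(x$elsets)) {
    if (nm %in% c("bone")) next
    lab[x$elsets[[nm]]] <- nm
  }
  cen <- element_centroids(x)
  tibble::tibble(element = seq_len(ne), set = lab,
                 x = cen[, 1], y = cen[, 2], z = cen[, 3],
                 volume = abs(tet_volumes(x$nodes, x$elements)))
}

# ---- INP-subset and STL I/O -------------------------------------------

#' Write / read a tet4 mesh in the INP subset format
#'
#' Supports the keyword subset `*NODE`, `*ELEMENT, TYPE=C3D4`,
#' `*ELSET, ELSET=name`, `*NSET, NSET=name` with plain comma-separated id
#' lists.
#'
#' @param mesh A `paosim_tet_mesh`.
#' @param path File path.
#' @return `read_mesh_inp()` returns a `paosim_tet_mesh` (without
#'   osteotomy-plane metadata unless present as a comment).
#' @export
write_mesh_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$elements)),
                     mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3], mesh$elements[, 4]), con)
  write_ids <- function(ids, header) {
    writeLines(header, con)
    if (length(ids) > 0) {
      chunks <- split(ids, ceiling(seq_along(ids) / 10))
      writeLines(vapply(chunks, paste, "", collapse = ", "), con)
    }
  }
  for (nm in names(mesh$elsets)) {
    write_ids(mesh$elsets[[nm]], sprintf("*ELSET, ELSET=%s", nm))
  }
  for (nm in names(mesh$nsets)) {
    write_ids(mesh$nsets[[nm]], sprintf("*NSET, NSET=%s", nm))
  }
  invisible(path)
}

#' @rdname write_mesh_inp
#' @export
read_mesh_inp <- function(path) {
  lines <- readLines(path)
  mode <- ""
  setname <- ""
  nodes <- list(); elems <- list(); elsets <- list(); nsets <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "**")) next
    if (startsWith(ln, "*")) {
      up <- toupper(ln)
      if (startsWith(up, "*NODE")) {
        mode <- "node"
      } else if (startsWith(up, "*ELEMENT")) {
        if (!grepl("TYPE=C3D4", up)) {
          stop_paosim("only C3D4 elements are supported",
                      "paosim_input_error")
        }
        mode <- "elem"
      } else if (startsWith(up, "*ELSET")) {
        mode <- "elset"
        setname <- sub(".*ELSET=([^,]+).*", "\\1", ln, ignore.case = TRUE)
        elsets[[setname]] <- integer()
      } else if (startsWith(up, "*NSET")) {
        mode <- "nset"
        setname <- sub(".*NSET=([^,]+).*", "\\1", ln, ignore.case = TRUE)
        nsets[[setname]] <- integer()
      } else {
        mode <- ""
      }
      next
    }
    vals <- as.numeric(strsplit(ln, ",")[[1]])
    if (mode == "node") {
      nodes[[length(nodes) + 1]] <- vals
    } else if (mode == "elem") {
      elems[[length(elems) + 1]] <- vals
    } else if (mode == "elset") {
      elsets[[setname]] <- c(elsets[[setname]], as.integer(vals))
    } else if (mode == "nset") {
      nsets[[setname]] <- c(nsets[[setname]], as.integer(vals))
    }
  }
  nm <- do.call(rbind, nodes)
  em <- do.call(rbind, elems)
  ids <- nm[, 1]
  nodes <- nm[order(ids), 2:4, drop = FALSE]
  em <- em[order(em[, 1]), , drop = FALSE]
  elements <- matrix(match(em[, 2:5], sort(ids)), ncol = 4)
  out <- list(nodes = nodes, elements = elements, elsets = elsets,
              nsets = nsets, osteotomy_plane = NULL,
              edge_size = NA_real_, spec = NULL)
  class(out) <- "paosim_tet_mesh"
  out
}

#' Write the boundary surface of a tet mesh as ASCII STL
#'
#' @param mesh A `paosim_tet_mesh`.
#' @param path File path.
#' @param name Solid name recorded in the file.
#' @export
write_surface_stl <- function(mesh, path, name = "paosim_surface") {
  el <- mesh$elements
  faces <- rbind(el[, c(1, 3, 2)], el[, c(1, 2, 4)],
                 el[, c(1, 4, 3)], el[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  bfaces <- faces[key %in% names(tab)[tab == 1], , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(bfaces))) {
    p <- mesh$nodes[bfaces[i, ], , drop = FALSE]
    n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(sprintf("  facet normal %.6g %.6g %.6g", n[1], n[2], n[3]),
               con)
    writeLines("    outer loop", con)
    writeLines(sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2],
                       p[, 3]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
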