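#' Reference frames for load transfer
#'
#' The finite-element model carries loads in a pelvis-fixed Cartesian frame
#' (conventionally the origin sits at the midpoint of the
#' posterior superior iliac spines, the XY plane passes through the pubic
#' symphysis midpoint perpendicular to the ground, the XZ plane parallel to
#' the ground). `load_frame()` records a rotation + origin; force vectors
#' transform by the rotation only.
#'
#' @param rotation 3 x 3 rotation matrix (musculoskeletal frame to mesh
#'   frame).
#' @param origin Frame origin, mm, recorded as metadata.
#' @param name Frame label.
#' @return A `paosim_frame` list.
#' @export
load_frame <- function(rotation = diag(3), origin = c(0, 0, 0),
                       name = "pelvis_psis") {
  stopifnot(all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop_paosim("rotation must be orthonormal", "paosim_config_error")
  }
  structure(list(rotation = rotation, origin = as.numeric(origin),
                 name = name), class = "paosim_frame")
}

#' Transform force vectors between frames
#' @param frame A `paosim_frame`.
#' @param v Matrix (n x 3) or length-3 vector.
#' @param inverse Apply the inverse rotation.
#' @return Transformed vectors, same shape.
#' @export
frame_transform <- function(frame, v, inverse = FALSE) {
  R <- if (inverse) t(frame$rotation) else frame$rotation
  if (is.null(dim(v))) drop(R %*% v) else t(R %*% t(v))
}

#' Build a finite-element load case from phase-aggregated loads
#'
#' Distributes each regional force over the nodes of its coupling patch so
#' that the nodal sum equals the force vector and the net moment about the
#' region centroid equals the prescribed moment (zero when none): the
#' static equivalents of the musculoskeletal hand-off. The hip contact
#' force goes to the joint patch; when muscle coupling is on, each muscle
#' group's pelvis-side resultant goes to its patch.
#'
#' @param mesh A `paosim_tet_mesh`.
#' @param forces Named list: region name -> force vector (N, length 3) or
#'   `list(force =, moment =)` with a moment in N mm about the region
#'   centroid.
#' @param fixed Node set name (or integer ids) to clamp (default
#'   `"fixed"`).
#' @param frame A `paosim_frame`; forces are rotated into the mesh frame.
#' @param phase Gait phase id (1-8) carried as metadata.
#' @return A `paosim_load_case`: `forces` (n_nodes x 3, N), `fixed_nodes`,
#'   `phase`, `frame`, `applied` (the per-region input).
#' @export
build_load_case <- function(mesh, forces, fixed = "fixed",
                            frame = load_frame(), phase = NA_integer_) {
  stopifnot(inherits(mesh, "paosim_tet_mesh"))
  nn <- nrow(mesh$nodes)
  F <- matrix(0, nn, 3)
  for (nm in names(forces)) {
    spec <- forces[[nm]]
    fvec <- if (is.list(spec)) as.numeric(spec$force) else as.numeric(spec)
    mom <- if (is.list(spec) && !is.null(spec$moment)) {
      as.numeric(spec$moment)
    } else c(0, 0, 0)
    ids <- if (is.character(nm) && nm %in% names(mesh$nsets)) {
      mesh$nsets[[nm]]
    } else NULL
    if (is.null(ids) || length(ids) == 0) {
      stop_paosim(sprintf("coupling region '%s' is missing or empty", nm),
                  "paosim_mapping_error")
    }
    fvec <- frame_transform(frame, fvec)
    mom <- frame_transform(frame, mom)
    k <- length(ids)
    F[ids, ] <- F[ids, , drop = FALSE] +
      matrix(fvec / k, k, 3, byrow = TRUE)
    if (any(mom != 0)) {
      if (k == 1) {
        stop_paosim(sprintf(
          "region '%s' has one node; cannot realise a moment", nm),
          "paosim_mapping_error")
      }
      r <- sweep(mesh$nodes[ids, , drop = FALSE], 2,
                 colMeans(mesh$nodes[ids, , drop = FALSE]))
      # minimal-norm nodal correction: sum(delta) = 0, sum(r x delta) = mom
      A <- matrix(0, 6, 3 * k)
      for (i in seq_len(k)) {
        A[1:3, (3 * i - 2):(3 * i)] <- diag(3)
        ri <- r[i, ]
        A[4:6, (3 * i - 2):(3 * i)] <-
          matrix(c(0, -ri[3], ri[2],
                   ri[3], 0, -ri[1],
                   -ri[2], ri[1], 0), 3, 3, byrow = TRUE)
      }
      sv <- svd(A)
      keep <- sv$d > 1e-10 * sv$d[1]
      delta <- sv$v[, keep, drop = FALSE] %*%
        (t(sv$u[, keep, drop = FALSE]) %*% c(0, 0, 0, mom) / sv$d[keep])
      F[ids, ] <- F[ids, , drop = FALSE] +
        matrix(delta, k, 3, byrow = TRUE)
    }
  }
  fixed_nodes <- if (is.character(fixed)) mesh$nsets[[fixed]] else fixed
  if (length(fixed_nodes) == 0) {
    stop_paosim("fixed node set is empty", "paosim_config_error")
  }
  structure(list(forces = F, fixed_nodes = sort(unique(fixed_nodes)),
                 fixed_values = NULL, phase = phase, frame = frame,
                 applied = forces),
            class = "paosim_load_case")
}

#' Build a load case from a uniform surface traction
#'
#' Converts a constant traction on a surface region into consistent nodal
#' forces: every boundary triangle whose nodes all belong to the region
#' contributes one third of `area * traction` to each of its nodes. This
#' is the exact (element-consistent) loading for linear triangles, so a
#' uniform traction produces a uniform stress field on a prismatic mesh.
#'
#' @param mesh A `paosim_tet_mesh`.
#' @param region Node set name or integer node ids defining the loaded
#'   surface.
#' @param traction Traction vector, MPa (N/mm^2).
#' @param fixed,frame,phase As in [build_load_case()].
#' @return A `paosim_load_case`.
#' @export
build_traction_load <- function(mesh, region, traction, fixed = "fixed",
                                frame = load_frame(), phase = NA_integer_) {
  ids <- if (is.character(region)) mesh$nsets[[region]] else region
  if (is.null(ids) || length(ids) == 0) {
    stop_paosim("traction region is missing or empty",
                "paosim_mapping_error")
  }
  tr <- frame_transform(frame, as.numeric(traction))
  el <- mesh$elements
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                 el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  bfaces <- faces[key %in% names(tab)[tab == 1], , drop = FALSE]
  in_region <- matrix(bfaces %in% ids, ncol = 3)
  bfaces <- bfaces[rowSums(in_region) == 3, , drop = FALSE]
  if (nrow(bfaces) == 0) {
    stop_paosim("no boundary faces lie entirely in the traction region",
                "paosim_mapping_error")
  }
  F <- matrix(0, nrow(mesh$nodes), 3)
  for (i in seq_len(nrow(bfaces))) {
    p <- mesh$nodes[bfaces[i, ], , drop = FALSE]
    a <- 0.5 * sqrt(sum(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
    for (j in 1:3) {
      F[bfaces[i, j], ] <- F[bfaces[i, j], ] + a * tr / 3
    }
  }
  fixed_nodes <- if (is.character(fixed)) mesh$nsets[[fixed]] else fixed
  if (length(fixed_nodes) == 0) {
    stop_paosim("fixed node set is empty", "paosim_config_error")
  }
  structure(list(forces = F, fixed_nodes = sort(unique(fixed_nodes)),
                 fixed_values = NULL, phase = phase, frame = frame,
                 applied = list(traction = traction, region = region)),
            class = "paosim_load_case")
}

# isotropic elasticity matrix (Voigt, engineering shear strains), MPa
.dmat <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# element B matrix (6 x 12) and volume for a tet4
.tet_b <- function(p) {
  M <- rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])
  detM <- det(M)
  V <- detM / 6
  invM <- solve(M)
  # gradients of barycentric shape functions
  g <- cbind(-rowSums(invM), invM)   # 3 x 4: columns are grad N_i
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    cidx <- (3 * a - 2):(3 * a)
    B[1, cidx[1]] <- g[1, a]
    B[2, cidx[2]] <- g[2, a]
    B[3, cidx[3]] <- g[3, a]
    B[4, cidx[1]] <- g[2, a]; B[4, cidx[2]] <- g[1, a]
    B[5, cidx[2]] <- g[3, a]; B[5, cidx[3]] <- g[2, a]
    B[6, cidx[1]] <- g[3, a]; B[6, cidx[3]] <- g[1, a]
  }
  list(B = B, V = V)
}

#' Solve the linear elastic problem on a tet4 mesh
#'
#' Assembles the global stiffness (constant-strain tetrahedra, one
#' integration point per element at the centroid), applies the load case,
#' eliminates fixed degrees of freedom (optionally with prescribed
#' displacements) and solves the sparse system. Units: mm, N, MPa.
#'
#' @param mesh A `paosim_tet_mesh`.
#' @param materials A `paosim_material_field` (per-element `E`, `nu`).
#' @param loadcase A `paosim_load_case`, or a list with `forces`
#'   (n_nodes x 3), `fixed_nodes`, optionally `fixed_values` (matrix of
#'   prescribed displacements for the fixed nodes, mm).
#' @return A `paosim_field_result`: `displacements` (n_nodes x 3, mm),
#'   `stress` / `strain` (n_el x 6, Voigt), `von_mises` (MPa),
#'   `principal_strain` (n_el x 3, sorted descending), `reactions`
#'   (fixed-node forces, N), `residual` (relative), plus references to the
#'   inputs.
#' @export
solve_linear_elasticity <- function(mesh, materials, loadcase) {
  nodes <- mesh$nodes
  el <- mesh$elements
  nn <- nrow(nodes)
  ne <- nrow(el)
  E <- materials$E
  nu <- materials$nu
  stopifnot(length(E) == ne)
  ii <- integer(144 * ne); jj <- integer(144 * ne); vv <- numeric(144 * ne)
  Blist <- vector("list", ne)
  Vol <- numeric(ne)
  Dlist <- vector("list", ne)
  pos <- 0
  idx12 <- function(en) as.vector(t(cbind(3 * en - 2, 3 * en - 1, 3 * en)))
  for (e in seq_len(ne)) {
    bb <- .tet_b(nodes[el[e, ], , drop = FALSE])
    D <- .dmat(E[e], nu[e])
    ke <- abs(bb$V) * crossprod(bb$B, D %*% bb$B)
    dofs <- idx12(el[e, ])
    ii[pos + 1:144] <- rep(dofs, times = 12)
    jj[pos + 1:144] <- rep(dofs, each = 12)
    vv[pos + 1:144] <- as.vector(ke)
    pos <- pos + 144
    Blist[[e]] <- bb$B
    Vol[e] <- abs(bb$V)
    Dlist[[e]] <- D
  }
  if (any(Vol <= 0)) {
    stop_paosim("mesh contains degenerate (zero-volume) elements",
                "paosim_input_error")
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(3 * nn, 3 * nn))
  Fv <- as.vector(t(loadcase$forces))
  fixed_nodes <- loadcase$fixed_nodes
  fixed_dofs <- as.vector(t(cbind(3 * fixed_nodes - 2, 3 * fixed_nodes - 1,
                                  3 * fixed_nodes)))
  u <- numeric(3 * nn)
  if (!is.null(loadcase$fixed_values)) {
    u[fixed_dofs] <- as.vector(t(loadcase$fixed_values))
  }
  free <- setdiff(seq_len(3 * nn), fixed_dofs)
  rhs <- Fv[free] - as.vector(K[free, fixed_dofs, drop = FALSE] %*%
                                u[fixed_dofs])
  Kff <- K[free, free]
  uf <- tryCatch(
    as.vector(Matrix::solve(Kff, rhs)),
    error = function(e) {
      stop_paosim(paste0(
        "stiffness system is singular; the fixed set leaves free ",
        "rigid-body modes (", conditionMessage(e), ")"),
        "paosim_solver_error")
    })
  u[free] <- uf
  res <- max(abs(Kff %*% uf - rhs)) / max(1, max(abs(Fv)))
  strain <- matrix(0, ne, 6)
  stress <- matrix(0, ne, 6)
  for (e in seq_len(ne)) {
    ue <- u[idx12(el[e, ])]
    eps <- drop(Blist[[e]] %*% ue)
    strain[e, ] <- eps
    stress[e, ] <- drop(Dlist[[e]] %*% eps)
  }
  vm <- von_mises_stress(stress)
  pstrain <- principal_strains(strain)
  Ku <- as.vector(K %*% u)
  reactions <- matrix(Ku - Fv, ncol = 3, byrow = TRUE)[fixed_nodes, ,
                                                       drop = FALSE]
  structure(list(displacements = matrix(u, ncol = 3, byrow = TRUE),
                 strain = strain, stress = stress, von_mises = vm,
                 principal_strain = pstrain, reactions = reactions,
                 element_volume = Vol, residual = res,
                 mesh = mesh, materials = materials, loadcase = loadcase),
            class = "paosim_field_result")
}

#' Von Mises stress from Voigt stress rows
#'
#' @param stress Matrix (n x 6) of stresses in Voigt order
#'   (xx, yy, zz, xy, yz, zx), MPa, or length-6 vector.
#' @return Numeric vector of von Mises stresses.
#' @export
von_mises_stress <- function(stress) {
  if (is.null(dim(stress))) stress <- matrix(stress, 1)
  sx <- stress[, 1]; sy <- stress[, 2]; sz <- stress[, 3]
  txy <- stress[, 4]; tyz <- stress[, 5]; tzx <- stress[, 6]
  sqrt(0.5 * ((sx - sy)^2 + (sy - sz)^2 + (sz - sx)^2) +
         3 * (txy^2 + tyz^2 + tzx^2))
}

#' Principal strains from Voigt strain rows
#'
#' Engineering shear strains are halved to tensor form before the
#' eigen-decomposition; rows of the result are sorted descending.
#'
#' @param strain Matrix (n x 6) in Voigt order (xx, yy, zz, xy, yz, zx) or
#'   length-6 vector.
#' @return Matrix (n x 3) of principal strains, descending.
#' @export
principal_strains <- function(strain) {
  if (is.null(dim(strain))) strain <- matrix(strain, 1)
  out <- matrix(0, nrow(strain), 3)
  for (i in seq_len(nrow(strain))) {
    e <- strain[i, ]
    Tm <- matrix(c(e[1], e[4] / 2, e[6] / 2,
                   e[4] / 2, e[2], e[5] / 2,
                   e[6] / 2, e[5] / 2, e[3]), 3, 3)
    out[i, ] <- sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  }
  out
}

#' Integration-point field metrics
#'
#' @param result A `paosim_field_result`.
#' @return Tibble with per-element von Mises stress and sorted principal
#'   strains.
#' @export
field_metrics <- function(result) {
  stopifnot(inherits(result, "paosim_field_result"))
  tibble::tibble(element = seq_along(result$von_mises),
                 von_mises = result$von_mises,
                 eps1 = result$principal_strain[, 1],
                 eps2 = result$principal_strain[, 2],
                 eps3 = result$principal_strain[, 3])
}

#' @export
tidy.paosim_field_result <- function(x, ...) field_metrics(x)

#' @export
glance.paosim_field_result <- function(x, ...) {
  tibble::tibble(max_von_mises = max(x$von_mises),
                 p100 = as.numeric(p100_mean(x$von_mises)),
                 max_displacement = max(sqrt(rowSums(x$displacements^2))),
                 residual = x$residual,
                 n_elements = length(x$von_mises))
}

#' Write a solved field as a legacy VTK unstructured grid
#'
#' Point data: displacement vectors; cell data: von Mises stress and
#' maximum principal strain.
#'
#' @param result A `paosim_field_result`.
#' @param path Output file path.
#' @export
write_field_vtk <- function(result, path) {
  mesh <- result$mesh
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "paosim field result", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1,
                     mesh$elements[, 2] - 1, mesh$elements[, 3] - 1,
                     mesh$elements[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("10", ne), con)
  writeLines(c(sprintf("POINT_DATA %d", nn),
               "VECTORS displacement double"), con)
  writeLines(sprintf("%.9g %.9g %.9g", result$displacements[, 1],
                     result$displacements[, 2], result$displacements[, 3]),
             con)
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", result$von_mises), con)
  writeLines(c("SCALARS max_principal_strain double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", result$principal_strain[, 1]), con)
  invisible(path)
}
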