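#' Map CT Hounsfield units to apparent bone mineral density
#'
#' Converts CT attenuation (Hounsfield units) to apparent bone mineral
#' density (g/cm^3) with the two-branch calibration used for pelvic bone:
#' values at or below -1 HU (air/soft tissue) map to zero density, values
#' above map linearly, `rho = (HU + 1.4246) * 0.001 / 1.058`.
#'
#' @param hu Numeric vector of Hounsfield unit values. Must be finite.
#' @return Numeric vector of apparent densities in g/cm^3 (never negative).
#' @examples
#' hu_to_density(c(-500, -1, 300, 1500))
#' @export
hu_to_density <- function(hu) {
  if (!is.numeric(hu) || any(!is.finite(hu))) {
    stop_paosim("`hu` must be finite numeric", "paosim_input_error")
  }
  rho <- (hu + 1.4246) * 0.001 / 1.058
  rho[hu <= -1] <- 0
  pmax(rho, 0)
}

#' Map apparent density to elastic modulus
#'
#' Power-law density-to-modulus relation `E = max(a * rho^b, e_min)`.
#' Defaults follow a published pelvic/femoral trabecular-cortical mapping
#' (a = 2017.3 MPa, b = 2.46) with a small floor so zero-density elements
#' keep a solvable stiffness.
#'
#' @param rho Numeric vector of apparent densities (g/cm^3), `>= 0`.
#' @param a Power-law coefficient in MPa; must be positive.
#' @param b Power-law exponent; must be positive.
#' @param e_min Modulus floor in MPa.
#' @return Numeric vector of elastic moduli in MPa.
#' @examples
#' density_to_modulus(c(0, 0.5, 1.2))
#' @export
density_to_modulus <- function(rho, a = 2017.3, b = 2.46, e_min = 1) {
  if (a <= 0 || b <= 0) {
    stop_paosim("power-law parameters `a` and `b` must be positive",
                "paosim_config_error")
  }
  if (any(rho < 0)) {
    stop_paosim("`rho` must be non-negative", "paosim_input_error")
  }
  pmax(a * rho^b, e_min)
}

#' Synthesize a per-element Hounsfield-unit field for a tetrahedral mesh
#'
#' Emulates the cortical/trabecular structure a CT scan would provide:
#' elements touching the outer surface receive cortical-level HU, interior
#' elements trabecular-level HU, with optional Gaussian noise. Screw
#' elements are flagged (their material is overridden later by
#' [assign_materials()]), not given bone HU.
#'
#' @param mesh A `paosim_tet_mesh` (see [generate_pelvis_mesh()]).
#' @param cortical_hu,trabecular_hu HU levels for surface-adjacent and
#'   interior bone elements.
#' @param noise_sd Standard deviation of additive HU noise.
#' @param seed Integer seed; the field is deterministic per seed.
#' @return A tibble with one row per element: `element`, `hu`,
#'   `is_screw`, `is_surface`.
#' @export
generate_density_field <- function(mesh, cortical_hu = 1500,
                                   trabecular_hu = 300, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(inherits(mesh, "paosim_tet_mesh"))
  ne <- nrow(mesh$elements)
  surf_nodes <- mesh_surface_nodes(mesh)
  on_surface <- matrix(mesh$elements %in% surf_nodes, ncol = 4)
  is_surface <- rowSums(on_surface) > 0
  is_screw <- rep(FALSE, ne)
  for (nm in names(mesh$elsets)) {
    if (startsWith(nm, "screw")) is_screw[mesh$elsets[[nm]]] <- TRUE
  }
  hu <- ifelse(is_surface, cortical_hu, trabecular_hu)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    hu <- hu + stats::rnorm(ne, 0, noise_sd)
  }
  hu[is_screw] <- NA_real_
  tibble::tibble(element = seq_len(ne), hu = hu,
                 is_screw = is_screw, is_surface = is_surface)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Assign element materials from a Hounsfield-unit field
#'
#' Bone elements get `E` from [hu_to_density()] composed with
#' [density_to_modulus()]. Elements whose centroid lies within
#' `callus_margin` of the osteotomy surface are degraded (modulus multiplied
#' by `degradation`), representing the healing callus band. Screw elements
#' receive the screw material (default titanium alloy) and are bonded to the
#' bone by construction (shared nodes).
#'
#' @param mesh A `paosim_tet_mesh`.
#' @param hu Per-element HU values (vector or the tibble from
#'   [generate_density_field()]).
#' @param callus_margin Margin around the osteotomy surface, mm (default
#'   10 mm = 1 cm).
#' @param degradation Multiplicative modulus weakening applied inside the
#'   callus band, in (0, 1].
#' @param screw_E,screw_nu Screw material (MPa, dimensionless).
#' @param bone_nu Poisson ratio for bone.
#' @param modulus_law List with `a`, `b`, `e_min` passed to
#'   [density_to_modulus()].
#' @return A `paosim_material_field` tibble: `element`, `rho`, `E`, `nu`,
#'   `is_screw`, `is_callus`.
#' @export
assign_materials <- function(mesh, hu, callus_margin = 10, degradation = 0.1,
                             screw_E = 110e3, screw_nu = 0.3, bone_nu = 0.3,
                             modulus_law = list(a = 2017.3, b = 2.46,
                                                e_min = 1)) {
  stopifnot(inherits(mesh, "paosim_tet_mesh"))
  if (is.data.frame(hu)) hu <- hu$hu
  ne <- nrow(mesh$elements)
  stopifnot(length(hu) == ne)
  if (callus_margin < 0 || degradation <= 0 || degradation > 1) {
    stop_paosim("need callus_margin >= 0 and 0 < degradation <= 1",
                "paosim_config_error")
  }
  is_screw <- rep(FALSE, ne)
  for (nm in names(mesh$elsets)) {
    if (startsWith(nm, "screw")) is_screw[mesh$elsets[[nm]]] <- TRUE
  }
  hu_bone <- ifelse(is_screw, 0, hu)
  hu_bone[is.na(hu_bone)] <- 0
  rho <- hu_to_density(hu_bone)
  E <- density_to_modulus(rho, a = modulus_law$a, b = modulus_law$b,
                          e_min = modulus_law$e_min)
  is_callus <- rep(FALSE, ne)
  if (callus_margin > 0) {
    if (is.null(mesh$osteotomy_plane)) {
      stop_paosim("mesh has no osteotomy surface; cannot place callus margin",
                  "paosim_config_error")
    }
    cen <- element_centroids(mesh)
    d <- abs(plane_signed_distance(cen, mesh$osteotomy_plane))
    is_callus <- d <= callus_margin & !is_screw
    E[is_callus] <- E[is_callus] * degradation
  }
  rho[is_screw] <- NA_real_
  E[is_screw] <- screw_E
  nu <- ifelse(is_screw, screw_nu, bone_nu)
  out <- tibble::tibble(element = seq_len(ne), rho = rho, E = E, nu = nu,
                        is_screw = is_screw, is_callus = is_callus)
  class(out) <- c("paosim_material_field", class(out))
  out
}
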