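# shared fixtures, all built in code

# structured tet4 bar with named end sets; dims in mm
make_bar_mesh <- function(dims = c(10, 10, 100), h = 5) {
  bm <- paosim:::.box_tet_mesh(dims, h)
  m <- list(nodes = bm$nodes, elements = bm$elements,
            elsets = list(bone = seq_len(nrow(bm$elements))),
            nsets = list(), osteotomy_plane = NULL, edge_size = h,
            spec = NULL)
  class(m) <- "paosim_tet_mesh"
  m$nsets$fixed <- which(m$nodes[, 3] > dims[3] - 1e-8)
  m$nsets$tip <- which(m$nodes[, 3] < 1e-8)
  m
}

uniform_materials <- function(mesh, E = 1000, nu = 0.3) {
  ne <- nrow(mesh$elements)
  out <- tibble::tibble(element = seq_len(ne), rho = 1,
                        E = rep(E, ne), nu = rep(nu, ne),
                        is_screw = rep(FALSE, ne),
                        is_callus = rep(FALSE, ne))
  class(out) <- c("paosim_material_field", class(out))
  out
}

# minimal normalized cycle tibble for direct inverse-dynamics input
make_cycle <- function(sag = rep(0, 101), fro = rep(0, 101),
                       tra = rep(0, 101), grf = matrix(0, 101, 3),
                       grm = matrix(0, 101, 3), mass = 65, Tcyc = 1.1) {
  out <- tibble::tibble(cycle_pct = seq(0, 100, length.out = 101),
                        angle_sagittal_deg = sag, angle_frontal_deg = fro,
                        angle_transverse_deg = tra,
                        grf_x_N = grf[, 1], grf_y_N = grf[, 2],
                        grf_z_N = grf[, 3],
                        grm_x_Nm = grm[, 1], grm_y_Nm = grm[, 2],
                        grm_z_Nm = grm[, 3])
  attr(out, "body_mass") <- mass
  attr(out, "cycle_duration_s") <- Tcyc
  attr(out, "events") <- c(heel_strike_1 = 0, toe_off = 0.62 * Tcyc,
                           heel_strike_2 = Tcyc)
  class(out) <- c("paosim_gait_cycle", class(out))
  out
}

# exhaustive k-medoid oracle: minimises total distance to nearest medoid
brute_force_medoids <- function(D, k) {
  n <- nrow(D)
  sets <- utils::combn(n, k)
  costs <- apply(sets, 2, function(med) {
    sum(apply(D[, med, drop = FALSE], 1, min))
  })
  sort(sets[, which.min(costs)])
}

local_noiseless_profile <- function(group) {
  cohort_profile(group, noise_sd = 0)
}
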