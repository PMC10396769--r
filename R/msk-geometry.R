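#' Scale generic maximum muscle strength to a subject
#'
#' Strength scaling from generic model to subject:
#' `F = F0 * (k_m / k_L) * (R_muscle_subject / R_muscle_generic)` with
#' `R_muscle = 0.5 - R_fat`, i.e. strength grows with the mass ratio,
#' shrinks with the height ratio, and is corrected by the relative
#' lean-mass fraction.
#'
#' @param F0 Generic maximum muscle strength, N.
#' @param k_m Subject/generic body-mass ratio (> 0).
#' @param k_L Subject/generic body-height ratio (> 0).
#' @param R_fat_subject,R_fat_generic Body-fat ratios in `[0, 0.5)`.
#' @return Scaled strength in N.
#' @examples
#' scale_strength(1000, k_m = 1.2, k_L = 1.1,
#'                R_fat_subject = 0.3, R_fat_generic = 0.25)
#' @export
scale_strength <- function(F0, k_m = 1, k_L = 1, R_fat_subject = 0.25,
                           R_fat_generic = 0.25) {
  if (k_m <= 0 || k_L <= 0) {
    stop_paosim("mass and height ratios must be positive",
                "paosim_domain_error")
  }
  rm_s <- 0.5 - R_fat_subject
  rm_g <- 0.5 - R_fat_generic
  if (rm_s <= 0 || rm_g <= 0) {
    stop_paosim("R_fat must be below 0.5 so the muscle ratio is positive",
                "paosim_domain_error")
  }
  F0 * (k_m / k_L) * (rm_s / rm_g)
}

#' Morph muscle attachment points between bone geometries
#'
#' Fits the least-squares affine transform mapping generic bony landmarks
#' onto subject landmarks and applies it to muscle attachment points — the
#' automatic re-seating of peri-ilium attachments when the generic ilium is
#' morphed to the subject's CT geometry.
#'
#' @param points Matrix (n x 3) of generic attachment points.
#' @param generic_landmarks,subject_landmarks Matrices (m x 3, `m >= 4`,
#'   non-coplanar) of paired landmarks.
#' @return Matrix (n x 3) of morphed points; the fitted transform is
#'   attached as attributes `A` (3 x 3) and `b`.
#' @export
morph_attachments <- function(points, generic_landmarks, subject_landmarks) {
  G <- as.matrix(generic_landmarks)
  S <- as.matrix(subject_landmarks)
  stopifnot(ncol(G) == 3, ncol(S) == 3, nrow(G) == nrow(S))
  if (nrow(G) < 4) {
    stop_paosim("need at least 4 landmark pairs", "paosim_rank_error")
  }
  Gc <- sweep(G, 2, colMeans(G))
  if (qr(Gc)$rank < 3) {
    stop_paosim("landmarks are coplanar or degenerate; affine fit is rank deficient",
                "paosim_rank_error")
  }
  X <- cbind(G, 1)
  # one least-squares fit per target coordinate: S = X %*% rbind(A^T, b^T)
  coef <- qr.solve(X, S)
  A <- t(coef[1:3, , drop = FALSE])
  b <- coef[4, ]
  P <- as.matrix(points)
  out <- P %*% t(A) + matrix(b, nrow(P), 3, byrow = TRUE)
  attr(out, "A") <- A
  attr(out, "b") <- b
  out
}

#' Define a muscle element
#'
#' A straight-line (or cylinder-wrapped) muscle element acting across the
#' hip: origin on the pelvis, insertion on the femur, a tensile strength
#' `N_i`, and optionally a wrapping cylinder (used for the iliopsoas, whose
#' path bends over the anterior pelvic brim).
#'
#' @param name Muscle name.
#' @param group One of `"extensor"`, `"flexor"`, `"abductor"`,
#'   `"adductor"`.
#' @param origin,insertion 3D points, m, in the hip-centred frame
#'   (x anterior, y lateral, z up; hip centre at the origin).
#' @param strength Tensile strength `N_i` in N (> 0).
#' @param wrap Optional list `(point, axis, radius)` defining the wrapping
#'   cylinder (m).
#' @return A `paosim_muscle` list.
#' @export
muscle_element <- function(name, group, origin, insertion, strength,
                           wrap = NULL) {
  group <- match.arg(group, c("extensor", "flexor", "abductor", "adductor"))
  if (strength <= 0) {
    stop_paosim("muscle strength must be positive", "paosim_config_error")
  }
  if (isTRUE(all.equal(origin, insertion))) {
    stop_paosim("origin and insertion coincide", "paosim_config_error")
  }
  structure(list(name = name, group = group, origin = as.numeric(origin),
                 insertion = as.numeric(insertion),
                 strength = as.numeric(strength), wrap = wrap),
            class = "paosim_muscle")
}

# Construct a straight-line muscle whose moment arm about the hip centre
# equals `arm` exactly: pick a pull direction u orthogonal to the arm
# (mostly vertical, as hip muscles run), set the insertion i = u x arm so
# that i x u = arm, and place the origin a segment length L up the line.
.muscle_from_arm <- function(name, group, arm, strength, length = 0.12) {
  a <- as.numeric(arm)
  an <- sqrt(sum(a^2))
  stopifnot(an > 0)
  ah <- a / an
  zh <- c(0, 0, 1)
  u <- zh - sum(zh * ah) * ah
  if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0) - ah[1] * ah
  u <- u / sqrt(sum(u^2))
  i <- cross3(u, a)
  muscle_element(name, group, origin = i + length * u, insertion = i,
                 strength = strength)
}

#' Default hip muscle set
#'
#' A reduced peri-ilium muscle model: twelve elements in the four
#' functional groups (extensors, flexors, abductors, adductors).
#' Attachment geometry is synthesized so that each element realises a
#' representative physiological moment-arm vector about the hip centre
#' (abduction/adduction, flexion/extension, rotation components of 1-6 cm),
#' giving a well-conditioned positive spanning set for the net-moment
#' demands of gait. The iliopsoas carries a wrapping cylinder at the
#' anterior pelvic brim. The superior part of gluteus maximus is grouped
#' with the abductors, matching its functional classification during gait.
#' Moment arms are held fixed over the cycle (quasi-static recruitment).
#'
#' @param strength_scale Multiplier applied to all strengths (use
#'   [scale_strength()] to derive it for a subject).
#' @return List of `paosim_muscle` elements.
#' @export
default_hip_muscles <- function(strength_scale = 1) {
  s <- strength_scale
  list(
    .muscle_from_arm("gluteus_maximus", "extensor",
                     c(0.005, 0.045, 0.015), 1500 * s),
    .muscle_from_arm("piriformis", "extensor",
                     c(0.010, 0.010, 0.030), 350 * s),
    muscle_element("iliopsoas", "flexor",
                   origin = c(0.025, -0.015, 0.09),
                   insertion = c(0.005, 0.015, -0.07), strength = 1200 * s,
                   wrap = list(point = c(0.035, 0, 0.015),
                               axis = c(0, 1, 0), radius = 0.022)),
    .muscle_from_arm("rectus_femoris", "flexor",
                     c(0.015, -0.045, 0.000), 850 * s),
    .muscle_from_arm("gluteus_medius", "abductor",
                     c(0.055, 0.005, -0.015), 1200 * s),
    .muscle_from_arm("gluteus_minimus", "abductor",
                     c(0.040, -0.010, -0.025), 450 * s),
    .muscle_from_arm("gluteus_maximus_superior", "abductor",
                     c(0.045, 0.025, 0.010), 600 * s),
    .muscle_from_arm("tensor_fasciae_latae", "abductor",
                     c(0.030, -0.030, -0.020), 300 * s),
    .muscle_from_arm("adductor_longus", "adductor",
                     c(-0.045, -0.025, -0.010), 650 * s),
    .muscle_from_arm("adductor_magnus", "adductor",
                     c(-0.055, 0.015, 0.005), 1100 * s),
    .muscle_from_arm("pectineus", "adductor",
                     c(-0.030, -0.020, -0.015), 350 * s),
    .muscle_from_arm("quadratus_femoris", "adductor",
                     c(-0.035, 0.010, 0.030), 300 * s)
  )
}

#' Shortest path of a muscle over a wrapping cylinder
#'
#' Computes the muscle path length and effective line of action between
#' origin and insertion in the presence of an optional wrapping cylinder.
#' When the straight segment misses the cylinder the path is straight;
#' otherwise the path is the tangent-arc-tangent geodesic: the problem is
#' solved in the plane normal to the cylinder axis and the axial travel is
#' recovered by unrolling (`L = sqrt(L_planar^2 + dz^2)`).
#'
#' @param muscle A `paosim_muscle` (wrap may be `NULL`).
#' @return List: `length` (m), `dir_origin`, `dir_insertion` (unit vectors
#'   pointing away from the respective endpoint along the path), `wrapped`.
#' @export
wrap_path <- function(muscle) {
  o <- muscle$origin
  i <- muscle$insertion
  straight <- function() {
    d <- o - i
    L <- sqrt(sum(d^2))
    list(length = L, dir_origin = (i - o) / L, dir_insertion = d / L,
         wrapped = FALSE)
  }
  w <- muscle$wrap
  if (is.null(w)) return(straight())
  a <- w$axis / sqrt(sum(w$axis^2))
  # orthonormal frame (e1, e2, a)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  to2d <- function(p) {
    d <- p - w$point
    c(sum(d * e1), sum(d * e2))
  }
  axial <- function(p) sum((p - w$point) * a)
  P <- to2d(o); Q <- to2d(i)
  rp <- sqrt(sum(P^2)); rq <- sqrt(sum(Q^2))
  R <- w$radius
  if (rp < R - 1e-12 || rq < R - 1e-12) {
    stop_paosim(sprintf("muscle '%s': endpoint lies inside its wrapping cylinder",
                        muscle$name), "paosim_geometry_error")
  }
  # distance from the 2D segment PQ to the cylinder centre
  seg <- Q - P
  tt <- if (sum(seg^2) > 0) {
    max(0, min(1, -sum(P * seg) / sum(seg^2)))
  } else 0
  dmin <- sqrt(sum((P + tt * seg)^2))
  phi <- acos(max(-1, min(1, sum(P * Q) / (rp * rq))))
  arc <- phi - acos(min(1, R / rp)) - acos(min(1, R / rq))
  if (dmin >= R - 1e-12 || arc <= 0) return(straight())
  tp <- sqrt(max(rp^2 - R^2, 0))
  tq <- sqrt(max(rq^2 - R^2, 0))
  Lpl <- tp + R * arc + tq
  dz <- axial(i) - axial(o)
  L <- sqrt(Lpl^2 + dz^2)
  # tangent points in 2D (choose the wrapping side consistently: the side
  # of the segment nearer the axis)
  tangent_pt <- function(Pv, rv, toward) {
    alpha <- acos(min(1, R / rv))
    # two candidate rotations of Pv/rv by +-alpha scaled to R
    rot <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                             sin(th) * v[1] + cos(th) * v[2])
    c1 <- rot(Pv / rv, alpha) * R
    c2 <- rot(Pv / rv, -alpha) * R
    # pick the tangent point nearer (in angle) to the other endpoint
    if (sum((c1 - toward)^2) < sum((c2 - toward)^2)) c1 else c2
  }
  Tp <- tangent_pt(P, rp, Q)
  Tq <- tangent_pt(Q, rq, P)
  slope <- dz / Lpl
  lift <- function(v2, h) w$point + v2[1] * e1 + v2[2] * e2 + h * a
  zo <- axial(o)
  Tp3 <- lift(Tp, zo + slope * tp)
  Tq3 <- lift(Tq, zo + slope * (tp + R * arc))
  do <- Tp3 - o
  di <- Tq3 - i
  list(length = L, dir_origin = do / sqrt(sum(do^2)),
       dir_insertion = di / sqrt(sum(di^2)), wrapped = TRUE)
}

#' Write / read a muscle model as JSON
#'
#' @param muscles List of `paosim_muscle` elements.
#' @param path File path.
#' @return `read_muscle_model()` returns the muscle list.
#' @export
write_muscle_model <- function(muscles, path) {
  x <- lapply(muscles, function(m) {
    list(name = m$name, group = m$group, origin = m$origin,
         insertion = m$insertion, strength = m$strength,
         wrap = m$wrap)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_muscle_model
#' @export
read_muscle_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  lapply(x, function(m) {
    wrap <- m$wrap
    if (!is.null(wrap)) {
      wrap <- list(point = as.numeric(wrap$point),
                   axis = as.numeric(wrap$axis),
                   radius = as.numeric(wrap$radius))
    }
    muscle_element(m$name, m$group, as.numeric(m$origin),
                   as.numeric(m$insertion), as.numeric(m$strength),
                   wrap = wrap)
  })
}
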