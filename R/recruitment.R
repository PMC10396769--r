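#' Build a muscle recruitment problem
#'
#' Assembles the moment-equilibrium system `C f = r` for a muscle set: each
#' column of `C` is the moment about the hip centre produced by unit force
#' along the muscle's effective line of action (wrap-aware), `r` is the net
#' hip moment the muscles must produce, and `N` collects the tensile
#' strengths.
#'
#' @param muscles List of `paosim_muscle` elements.
#' @param r Net hip moment, N m (length 3).
#' @param p Recruitment exponent (>= 1; the default cubic criterion is 3).
#' @return A `paosim_recruitment_problem` list with `C`, `r`, `N`, `p`,
#'   `lines` (3 x n matrix of unit lines of action at the insertion) and
#'   `names`.
#' @export
build_recruitment_problem <- function(muscles, r, p = 3) {
  n <- length(muscles)
  C <- matrix(0, 3, n)
  U <- matrix(0, 3, n)
  N <- numeric(n)
  for (j in seq_len(n)) {
    m <- muscles[[j]]
    path <- wrap_path(m)
    u <- path$dir_insertion            # pulls the femur toward the pelvis
    U[, j] <- u
    C[, j] <- cross3(m$insertion, u)   # moment about the hip centre
    N[j] <- m$strength
  }
  structure(list(C = C, r = as.numeric(r), N = N, p = p, lines = U,
                 names = vapply(muscles, `[[`, "", "name")),
            class = "paosim_recruitment_problem")
}

# non-negative least squares min ||Cx - r|| by cyclic coordinate descent;
# small dense problems only (feasibility diagnostics)
nnls_cd <- function(C, r, iters = 2000, tol = 1e-12) {
  n <- ncol(C)
  G <- crossprod(C)
  h <- drop(crossprod(C, r))
  x <- rep(0, n)
  dg <- diag(G)
  dg[dg == 0] <- 1
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_len(n)) {
      xj <- max(0, x[j] + (h[j] - sum(G[j, ] * x)) / dg[j])
      delta <- max(delta, abs(xj - x[j]))
      x[j] <- xj
    }
    if (delta < tol * (1 + max(abs(x)))) break
  }
  x
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Solve the polynomial muscle recruitment problem
#'
#' Distributes the net joint moment among redundant muscles by minimising
#' the polynomial criterion `sum_i (f_i / N_i)^p` subject to the
#' equilibrium constraints `C f = r` and non-negativity `f >= 0`. The
#' solver works on the KKT system: for active muscles the stationarity
#' condition gives the closed form
#' `f_i = N_i * (N_i * max(0, (C' lambda)_i) / p)^(1/(p-1))`,
#' and the equality multipliers `lambda` are found by a damped
#' (Levenberg-regularised) Newton iteration on `C f(lambda) = r`.
#'
#' @param problem A `paosim_recruitment_problem` (or a list with `C`, `r`,
#'   `N`, `p`).
#' @param tol Constraint tolerance: converged when
#'   `max|C f - r| <= tol * (1 + max|r|)`.
#' @param max_iter Maximum Newton iterations.
#' @param lambda0 Optional warm start for the multipliers.
#' @return Numeric force vector `f` (N) with attributes `lambda`,
#'   `residual` (max constraint violation) and `objective`.
#' @examples
#' pr <- list(C = matrix(0.05, 1, 1), r = 10, N = 1000, p = 3)
#' recruit_muscles(pr)  # forced by the equality: f = 200 N
#' @export
recruit_muscles <- function(problem, tol = 1e-9, max_iter = 300,
                            lambda0 = NULL) {
  C <- as.matrix(problem$C)
  r <- as.numeric(problem$r)
  N <- as.numeric(problem$N)
  p <- problem$p %||% 3
  m <- nrow(C); n <- ncol(C)
  stopifnot(length(r) == m, length(N) == n)
  if (p <= 1) {
    stop_paosim("recruitment exponent p must exceed 1 for the smooth criterion",
                "paosim_config_error")
  }
  rn <- max(abs(r))
  done <- function(f, lam) {
    res <- max(abs(C %*% f - r))
    structure(as.numeric(f), lambda = lam, residual = res,
              objective = sum((f / N)^p), names = problem$names %||% NULL)
  }
  if (rn == 0) return(done(rep(0, n), rep(0, m)))
  q <- 1 / (p - 1)
  ffun <- function(lam) {
    s <- pmax(drop(crossprod(C, lam)), 0)
    N * (N * s / p)^q
  }
  wfun <- function(lam) {
    s <- drop(crossprod(C, lam))
    w <- numeric(n)
    pos <- s > 0
    # d f_i / d s_i for active muscles
    w[pos] <- N[pos]^(1 + q) * q * s[pos]^(q - 1) / p^q
    pmin(w, 1e12)
  }
  # start: least-squares direction, magnitude set by the q-homogeneity of f
  lam <- lambda0
  if (is.null(lam)) {
    A <- tcrossprod(C) + diag(1e-10, m)
    lam <- drop(solve(A, r))
    g0 <- sqrt(sum((C %*% ffun(lam))^2))
    if (g0 < 1e-300) {
      lam <- lam * 0 + 1e-6
      g0 <- sqrt(sum((C %*% ffun(lam))^2))
    }
    if (g0 > 0) lam <- lam * (sqrt(sum(r^2)) / g0)^(1 / q)
  }
  # stage 1: maximise the smooth concave dual
  #   D(lambda) = sum_i phi_i(s_i) + lambda' r,  s = C' lambda,
  # where phi_i is the per-muscle partial minimisation; grad D = r - C f.
  negD <- function(lam) {
    s <- pmax(drop(crossprod(C, lam)), 0)
    f <- N * (N * s / p)^q
    -(sum((f / N)^p - s * f) + sum(lam * r))
  }
  negDgrad <- function(lam) {
    drop(C %*% ffun(lam) - r)
  }
  sc <- max(abs(lam), 1e-8)
  opt <- stats::optim(lam, negD, negDgrad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15,
                                     parscale = rep(sc, m)))
  if (max(abs(negDgrad(opt$par))) < max(abs(negDgrad(lam)))) lam <- opt$par
  mu <- 1e-8
  f <- ffun(lam)
  g <- drop(C %*% f - r)
  best <- list(lam = lam, gn = max(abs(g)))
  for (it in seq_len(max_iter)) {
    gn <- max(abs(g))
    if (gn <= tol * (1 + rn)) break
    J <- C %*% (wfun(lam) * t(C))
    step <- tryCatch(drop(solve(J + diag(mu * (1 + max(diag(J))), m), -g)),
                     error = function(e) NULL)
    if (is.null(step)) {
      mu <- mu * 10
      next
    }
    lam_new <- lam + step
    g_new <- drop(C %*% ffun(lam_new) - r)
    if (max(abs(g_new)) < gn) {
      lam <- lam_new
      g <- g_new
      mu <- max(mu / 3, 1e-12)
      if (max(abs(g)) < best$gn) best <- list(lam = lam, gn = max(abs(g)))
    } else {
      # damped step
      ok <- FALSE
      alf <- 0.5
      for (ls in 1:25) {
        lam_try <- lam + alf * step
        g_try <- drop(C %*% ffun(lam_try) - r)
        if (max(abs(g_try)) < gn) {
          lam <- lam_try; g <- g_try; ok <- TRUE
          if (max(abs(g)) < best$gn) best <- list(lam = lam, gn = max(abs(g)))
          break
        }
        alf <- alf / 2
      }
      if (!ok) mu <- mu * 10
      if (mu > 1e8) break
    }
  }
  f <- ffun(best$lam)
  res <- max(abs(C %*% f - r))
  if (res > 1e-6 * (1 + rn)) {
    # feasibility diagnostic: best non-negative least-squares fit
    feas <- nnls_cd(C, r)
    feas_res <- max(abs(C %*% feas - r))
    if (feas_res > 1e-4 * (1 + rn)) {
      stop_paosim(sprintf(paste0(
        "recruitment problem is infeasible: best non-negative fit leaves ",
        "residual %.3g (|r| = %.3g)"), feas_res, rn),
        "paosim_infeasible_error")
    }
    stop_paosim(sprintf(paste0(
      "recruitment solver did not reach tolerance: residual %.3g ",
      "(|r| = %.3g)"), res, rn), "paosim_solver_error")
  }
  done(f, best$lam)
}
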