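# Discrete axisymmetric model of a growing cell sheet on a frictional
# substrate.
#
# The sheet is a 1D radial chain of linear-elastic elements (the
# equibiaxial reduction of the plate problem: hoop and radial stress are
# taken equal, consistent with the closed-form shear-lag solution).
# Element i spans nodes (i-1, i) with rest length l_i; its compressive
# stress is sigma_i = E_eff (1 - L_i / l_i), L_i the current length.
# Each node is pinned to the substrate by rate-independent Coulomb
# friction of constant traction magnitude f acting over its tributary
# interface length; it moves only while the net elastic force exceeds
# that capacity. Growth multiplies rest lengths by exp(g dt) per step;
# tissue fluidity enters as Maxwell stress relaxation with timescale tau
# (sigma <- sigma exp(-dt/tau), implemented as rest-length creep).
# An element delaminates -- irreversibly -- when its stored elastic
# energy per interface area, sigma^2 h / (2 E_eff), reaches the adhesion
# energy Gamma; its interfacial coupling is then removed. Delamination
# is the model's readout for the onset of stratification; post-buckling
# shape is not simulated.
#
# In the fully mobilised solid limit (tau = Inf, all nodes sliding) the
# equilibrium stress drop across node j is exactly f * (tributary
# length) / h, so the discrete profile reproduces the shear-lag solution
# sigma(r) = f (R - r) / h at element midpoints up to solver tolerance --
# the constant-traction law makes the analytic oracle exact.
#
# Quasi-static solve: active-set Coulomb iteration. Given a trial
# stick/slip assignment, slipping nodes satisfy a tridiagonal linear
# balance (elastic force = signed friction capacity) solved exactly by
# the Thomas algorithm; stick/slip sets are updated until consistent
# (force residual below 1e-8 of the friction force scale). Deterministic;
# the seed only jitters the optional initial geometry.

#' Simulator parameters
#'
#' @param n_elements number of radial elements (>= 50 recommended; >= 4
#'   enforced).
#' @param growth_rate isotropic rest-length growth rate g (1/h).
#' @param E_eff effective sheet modulus (Pa).
#' @param h sheet thickness (µm).
#' @param f interfacial shear traction magnitude (Pa).
#' @param Gamma interfacial adhesion energy (J/m²); `Inf` = never
#'   delaminates.
#' @param tau Maxwell stress-relaxation time (h); `Inf` = solid-like
#'   (jammed) tissue.
#' @param dt time step (h); must satisfy `dt <= tau/10` (tau finite) and
#'   `g dt <= 0.01`.
#' @param t_end end time (h).
#' @param R0 initial colony radius (µm).
#' @param friction_ratio_map optional function(r_frac in [0,1]) -> factor
#'   multiplying f (heterogeneous cell-substrate interaction).
#' @param seed integer seed (only used for `jitter`).
#' @param jitter relative jitter of initial node spacing (0 = regular).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_elements = 200L, growth_rate = 0.05, E_eff = 1000,
                       h = 10, f = 1, Gamma = Inf, tau = Inf, dt = NULL,
                       t_end = 20, R0 = 50, friction_ratio_map = NULL,
                       seed = 1L, jitter = 0) {
  n_elements <- as.integer(n_elements)
  stopifnot(n_elements >= 4L, growth_rate >= 0, E_eff > 0, h > 0, f >= 0,
            Gamma >= 0, tau > 0, t_end > 0, R0 > 0, jitter >= 0)
  if (is.null(dt)) {
    dt <- min(if (is.finite(tau)) tau / 10 else Inf,
              if (growth_rate > 0) 0.01 / growth_rate else t_end / 10,
              t_end / 10)
  }
  stopifnot(dt > 0, growth_rate * dt <= 0.01 + 1e-12)
  if (is.finite(tau) && dt > tau / 10 + 1e-12) {
    stop("dt must be <= tau/10 for a finite relaxation time", call. = FALSE)
  }
  structure(list(n_elements = n_elements, growth_rate = growth_rate,
                 E_eff = E_eff, h = h, f = f, Gamma = Gamma, tau = tau,
                 dt = dt, t_end = t_end, R0 = R0,
                 friction_ratio_map = friction_ratio_map,
                 seed = as.integer(seed), jitter = jitter),
            class = "sim_params")
}

#' Initial sheet state
#'
#' Stress-free sheet of radius R0 with (optionally jittered) regular node
#' spacing.
#'
#' @param params a [sim_params()].
#' @return object of class `sheet_state` with node radii `r` (µm, node 0
#'   pinned at the centre), element rest lengths `l`, stresses `sigma`
#'   (Pa, compression positive), `delaminated` flags and `time`.
#' @export
sheet_init <- function(params) {
  n <- params$n_elements
  r <- seq(0, params$R0, length.out = n + 1L)
  if (params$jitter > 0) {
    u <- .with_seed(params$seed, stats::runif(n))
    dr <- diff(r)
    dr <- dr * (1 + params$jitter * (u - 0.5))
    r <- c(0, cumsum(dr)) * params$R0 / sum(dr)
  }
  structure(list(r = r, l = diff(r), sigma = numeric(n),
                 delaminated = logical(n), time = 0,
                 onset = NULL, slip_sign = rep(0L, n)),
            class = "sheet_state")
}

#' @export
print.sheet_state <- function(x, ...) {
  cat("<sheet_state> t =", signif(x$time, 4), "h | R =",
      signif(max(x$r), 5), "um | max sigma =", signif(max(x$sigma), 4),
      "Pa |", sum(x$delaminated), "delaminated element(s)\n")
  invisible(x)
}

# friction traction at node positions (Pa), applying the optional map
.node_traction <- function(params, r, R) {
  if (is.null(params$friction_ratio_map)) {
    rep(params$f, length(r))
  } else {
    params$f * params$friction_ratio_map(pmin(1, r / max(R, 1e-12)))
  }
}

# friction capacity per node (Pa*µm, force per unit circumferential
# width): traction times the tributary length of *attached* adjacent
# element halves
.node_capacity <- function(params, r, delam) {
  n <- length(r) - 1L
  L <- diff(r)
  half <- L / 2 * as.numeric(!delam)
  trib <- c(half[1:(n - 1L)] + half[2:n], half[n])   # nodes 1..n
  fr <- .node_traction(params, r[-1L], max(r))
  fr * trib
}

# Quasi-static Coulomb equilibrium.
#
# The incremental state minimises the convex energy
#   sum_i k_i/2 (L_i - l_i)^2 + sum_j C_j |r_j - r0_j|,
# with k_i = E h / l_i the element stiffness and C_j the node's friction
# capacity (constant traction times attached tributary length); the L1
# term is the work dissipated against constant-magnitude friction during
# the step. Solved by a primal active-set method: nodes are either stuck
# (pinned at their start-of-step position) or slipping with a known sign
# (friction force at capacity opposing the motion). Each iteration solves
# the resulting tridiagonal system exactly (Thomas algorithm), takes the
# longest step that keeps every slip sign consistent, and updates the
# stick/slip assignment (release the most violated stuck node, re-stick
# any slip node driven back to its origin). Finite termination; the
# stick/slip pattern warm-starts from the previous time step. The
# position-dependent capacities are refreshed in an outer loop until
# stable; Karush-Kuhn-Tucker residuals are verified to 1e-8 of the
# friction force scale.
#
# r0: start-of-step node radii (length n+1, r0[1] = 0 pinned at the
# centre); l: grown rest lengths. Returns list(r, slip_sign).
.solve_quasistatic <- function(r0, l, params, delam, warm_sign = NULL,
                               max_iter = 100000L) {
  n <- length(l)
  E <- params$E_eff; h <- params$h
  if (params$f == 0) {                       # frictionless: stress-free
    return(list(r = c(0, cumsum(l)), slip_sign = rep(1L, n)))
  }
  kEh <- h * E
  k <- kEh / l
  tiny <- 1e-12 * max(r0[n + 1L], 1)
  F_at <- function(rv) {
    sig <- E * (1 - diff(rv) / l)
    h * c(sig[1:(n - 1L)] - sig[2:n], sig[n])
  }
  solve_set <- function(sgn, C) {            # sgn: 0 stuck, +-1 slip
    lowd <- numeric(n); diag_ <- numeric(n); upd <- numeric(n)
    rhs <- numeric(n)
    slip <- sgn != 0L
    for (j in seq_len(n)) {
      if (slip[j]) {
        if (j < n) {
          lowd[j] <- k[j]; diag_[j] <- -(k[j] + k[j + 1L])
          upd[j] <- k[j + 1L]; rhs[j] <- sgn[j] * C[j]
        } else {
          lowd[j] <- k[n]; diag_[j] <- -k[n]
          rhs[j] <- sgn[j] * C[j] - kEh
        }
      } else {
        diag_[j] <- 1; rhs[j] <- r0[j + 1L]
      }
    }
    c(0, .thomas(lowd, diag_, upd, rhs))
  }
  r <- r0
  sgn <- if (is.null(warm_sign)) rep(0L, n) else as.integer(warm_sign)
  iter <- 0L
  for (outer in 1:50) {
    C <- .node_capacity(params, r, delam)
    tol_F <- 1e-8 * max(max(C), kEh * 1e-12)
    # drop warm-started slip states that are not actually loaded
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("quasi-static solve did not converge within ", max_iter,
             " active-set iterations (residual report: max excess force ",
             signif(max(pmax(abs(F_at(r)) - C, 0)), 4), " Pa*um)",
             call. = FALSE)
      }
      r_star <- solve_set(sgn, C)
      # line search: stop where a slip node would cross its origin
      dr <- r_star[-1L] - r[-1L]
      off <- r[-1L] - r0[-1L]
      alpha <- 1
      block <- 0L
      for (j in which(sgn != 0L)) {
        tgt <- off[j] + dr[j]
        if (abs(dr[j]) > 0 && sign(tgt) == -sgn[j] && tgt != 0) {
          aj <- -off[j] / dr[j]
          if (aj < alpha - 1e-15) { alpha <- max(aj, 0); block <- j }
        }
      }
      r[-1L] <- r[-1L] + alpha * dr
      if (block > 0L) {
        sgn[block] <- 0L               # node driven back to origin: stick
        r[block + 1L] <- r0[block + 1L]
        next
      }
      # full step taken: check stuck-node optimality
      Fv <- F_at(r)
      stuck <- which(sgn == 0L)
      viol <- abs(Fv[stuck]) - C[stuck]
      if (length(stuck) == 0L || max(viol) <= tol_F) break
      w <- stuck[which.max(viol)]      # release the most violated node
      sgn[w] <- as.integer(sign(Fv[w]))
    }
    C2 <- .node_capacity(params, r, delam)
    if (max(abs(C2 - C)) <= 1e-9 * max(max(C), 1e-300)) {
      return(list(r = r, slip_sign = sgn))
    }
  }
  stop("quasi-static solve: friction capacities failed to stabilise",
       call. = FALSE)
}

# Thomas algorithm for a tridiagonal system; lowd[1] is ignored.
.thomas <- function(lowd, diag_, upd, rhs) {
  n <- length(diag_)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upd[1] / diag_[1]
  dp[1] <- rhs[1] / diag_[1]
  for (j in 2:n) {
    m <- diag_[j] - lowd[j] * cp[j - 1L]
    cp[j] <- upd[j] / m
    dp[j] <- (rhs[j] - lowd[j] * dp[j - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (j in (n - 1L):1L) x[j] <- dp[j] - cp[j] * x[j + 1L]
  x
}

#' Advance the sheet by one time step
#'
#' One step = grow rest lengths by `exp(g dt)`, re-solve the quasi-static
#' Coulomb balance, apply Maxwell relaxation `sigma <- sigma exp(-dt/tau)`
#' (as rest-length creep; relaxation only lowers forces, so equilibrium
#' is preserved), then flag elements whose stored energy reaches Gamma as
#' delaminated (absorbing).
#'
#' @param state a `sheet_state`.
#' @param params a [sim_params()].
#' @return the advanced `sheet_state`.
#' @export
sim_step <- function(state, params) {
  stopifnot(inherits(state, "sheet_state"), inherits(params, "sim_params"))
  n <- params$n_elements
  l <- state$l * exp(params$growth_rate * params$dt)
  sol <- .solve_quasistatic(state$r, l, params, state$delaminated,
                            warm_sign = state$slip_sign)
  r <- sol$r
  L <- diff(r)
  sigma <- params$E_eff * (1 - L / l)
  if (is.finite(params$tau)) {
    rho <- exp(-params$dt / params$tau)
    sigma <- sigma * rho
    l <- L / (1 - sigma / params$E_eff)   # creep rest lengths to match
  }
  delam <- state$delaminated |
    (.energy_si(pmax(sigma, 0), params$h, params$E_eff) >= params$Gamma)
  onset <- state$onset
  if (is.null(onset) && any(delam)) {
    onset <- list(time = state$time + params$dt, R = max(r),
                  n_delaminated = sum(delam))
  }
  structure(list(r = r, l = l, sigma = sigma, delaminated = delam,
                 time = state$time + params$dt, onset = onset,
                 slip_sign = sol$slip_sign),
            class = "sheet_state")
}

#' Integrate sheet growth
#'
#' Runs [sim_step()] to `t_end` or (optionally) to the first delamination,
#' recording R(t), the centre stress, and stress snapshots at requested
#' times.
#'
#' @param params a [sim_params()].
#' @param stop_at_onset stop as soon as any element delaminates.
#' @param snapshot_times times (h) at which to store [stress_snapshot()]s;
#'   the final state is always stored.
#' @return list with `state` (final), `trajectory` (data.frame time, R,
#'   sigma_max, n_delaminated), `snapshots`, and `onset` (list(time, R) or
#'   NULL when the sheet never delaminates).
#' @export
run_growth <- function(params, stop_at_onset = TRUE, snapshot_times = NULL) {
  state <- sheet_init(params)
  nsteps <- ceiling(params$t_end / params$dt - 1e-9)
  traj_t <- numeric(0); traj_R <- numeric(0); traj_s <- numeric(0)
  traj_d <- integer(0)
  snaps <- list()
  next_snap <- if (is.null(snapshot_times)) numeric(0) else
    sort(snapshot_times)
  for (i in seq_len(nsteps)) {
    state <- sim_step(state, params)
    traj_t <- c(traj_t, state$time)
    traj_R <- c(traj_R, max(state$r))
    traj_s <- c(traj_s, max(state$sigma))
    traj_d <- c(traj_d, sum(state$delaminated))
    while (length(next_snap) > 0L && state$time >= next_snap[1] - 1e-9) {
      snaps[[length(snaps) + 1L]] <- stress_snapshot(state)
      next_snap <- next_snap[-1L]
    }
    if (stop_at_onset && !is.null(state$onset)) break
  }
  snaps[[length(snaps) + 1L]] <- stress_snapshot(state)
  list(state = state,
       trajectory = data.frame(time = traj_t, R = traj_R,
                               sigma_max = traj_s,
                               n_delaminated = traj_d),
       snapshots = snaps,
       onset = state$onset)
}

#' Element-centred stress snapshot
#'
#' @param state a `sheet_state`.
#' @return data.frame with `r` (element midpoints, µm), `sigma` (Pa),
#'   `delaminated`, plus attributes `time` and `R`; directly comparable
#'   with [stress_profile()].
#' @export
stress_snapshot <- function(state) {
  stopifnot(inherits(state, "sheet_state"))
  mid <- (state$r[-1L] + state$r[-length(state$r)]) / 2
  out <- data.frame(r = mid, sigma = state$sigma,
                    delaminated = state$delaminated)
  attr(out, "time") <- state$time
  attr(out, "R") <- max(state$r)
  out
}

#' Stratification phase diagram
#'
#' Runs [run_growth()] on every row of a parameter grid and tabulates
#' whether the sheet stratifies (delaminates) and at what radius. In the
#' solid limit the onset radius decreases with f and increases with
#' Gamma; lowering tau shrinks and eventually empties the stratifying
#' region -- the 2D (fluid) versus 3D (solid) morphogenesis dichotomy.
#'
#' @param grid data.frame with columns among `f`, `Gamma`, `tau`
#'   overriding the base parameters row by row.
#' @param base a [sim_params()] supplying all other parameters.
#' @return `grid` augmented with `stratifies` (logical), `onset_R` (µm,
#'   NA when it never delaminates) and `onset_time` (h).
#' @export
phase_diagram <- function(grid, base) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0L,
            inherits(base, "sim_params"))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- unclass(base)
    for (nm in intersect(names(grid), c("f", "Gamma", "tau"))) {
      p[[nm]] <- grid[[nm]][i]
    }
    p$dt <- NULL                       # re-derive dt from the new tau/g
    p <- do.call(sim_params, p)
    out <- run_growth(p, stop_at_onset = TRUE)
    if (is.null(out$onset)) {
      c(stratifies = 0, onset_R = NA_real_, onset_time = NA_real_)
    } else {
      c(stratifies = 1, onset_R = out$onset$R, onset_time = out$onset$time)
    }
  })
  res <- do.call(rbind, res)
  cbind(grid, stratifies = res[, "stratifies"] > 0,
        onset_R = res[, "onset_R"], onset_time = res[, "onset_time"])
}
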