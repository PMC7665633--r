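# Numerical cross-validation: forward sensitivities, the elasticity
# (relative sensitivity) matrix, its column-dependence structure, and finite
# scaling of trajectories.
#
# The variational system dS/dt = (df/dx) S + df/dtheta is integrated
# alongside the states; sensitivity columns cover every declared parameter
# and the initial condition of every state (S(0) = 0 for parameter columns,
# identity for IC columns). Elasticities K_ij = theta_j / x_i * S_ij are the
# log-log sensitivities: K_ij = 1 means a 10% bump in theta_j moves x_i by
# 10%. A symmetry generator predicts an exact linear dependence among the
# columns of K; the residual of that combination is the numerical check of
# the symbolic verdict.

.ic_value <- function(model, state, parameter_values) {
  ic <- model$init[[state]]
  switch(ic$kind,
         known_zero = 0,
         known_value = ic$value,
         unknown_parameter = {
           v <- parameter_values[[ic$value]]
           if (is.null(v)) sid_error(sprintf(
             "no value supplied for IC parameter '%s'", ic$value),
             "scalesid_eval_error")
           v
         })
}

#' Sample a generic test point for a model
#'
#' Parameters (including IC parameters) are drawn log-uniformly on
#' `[1/2, 2]`: generic positive values away from poles and from special
#' algebraic loci.
#'
#' @param model a [ode_model()].
#' @param seed RNG seed.
#' @return named numeric vector over `c(params, ic_params)`.
#' @export
sid_test_point <- function(model, seed = 0) {
  nms <- c(model$params, model$ic_params)
  with_seed(seed, {
    v <- exp(stats::runif(length(nms), log(0.5), log(2)))
    structure(v, names = nms)
  })
}

#' Integrate a model (no sensitivities)
#'
#' @param model a [ode_model()].
#' @param parameter_values named values for all parameters and IC parameters.
#' @param times strictly increasing time grid.
#' @param rtol,atol integration tolerances (lsoda).
#' @param ic_override optional named vector overriding initial conditions.
#' @return deSolve matrix: time column followed by one column per state.
#' @export
simulate_model <- function(model, parameter_values, times,
                           rtol = 1e-10, atol = 1e-12, ic_override = NULL) {
  x0 <- vapply(model$states, .ic_value, numeric(1), model = model,
               parameter_values = as.list(parameter_values))
  if (!is.null(ic_override)) x0[names(ic_override)] <- ic_override
  pv <- as.list(parameter_values)
  rhs <- model$rhs
  func <- function(t, y, parms) {
    env <- c(as.list(structure(y, names = model$states)), pv)
    list(vapply(rhs, function(e) as.numeric(eval_num(e, env)), numeric(1)))
  }
  sol <- deSolve::ode(y = x0, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    sid_error(sprintf("integration failed near t = %g", sol[nrow(sol), 1]),
              "scalesid_integration_failure")
  }
  sol
}

#' Integrate a model together with its forward sensitivities
#'
#' @param model a [ode_model()].
#' @param parameter_values named vector/list of values for every parameter
#'   and IC parameter; defaults to [sid_test_point()].
#' @param times strictly increasing time grid.
#' @param rtol,atol integration tolerances (lsoda).
#' @return An object of class `sid_traj` holding the time grid, the solution
#'   `x`, the sensitivity array `S` (time x state x column) with one column
#'   per parameter and per state initial condition (`<state>_0`), column
#'   multipliers `col_values`, and integration metadata.
#' @export
simulate_with_sensitivities <- function(model, parameter_values = NULL,
                                        times = seq(0, 1, length.out = 41),
                                        rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(model, "sid_model"))
  if (is.null(parameter_values)) parameter_values <- sid_test_point(model)
  pv <- as.list(parameter_values)
  n <- length(model$states)
  pars <- model$params
  m <- length(pars)
  cols <- c(pars, paste0(model$states, "_0"))
  nc <- m + n

  x0 <- vapply(model$states, .ic_value, numeric(1), model = model,
               parameter_values = pv)
  jac_x <- lapply(model$rhs, function(f)
    lapply(model$states, function(s) expr_deriv(f, s)))
  jac_p <- lapply(model$rhs, function(f)
    lapply(pars, function(p) expr_deriv(f, p)))

  S0 <- matrix(0, n, nc)
  S0[, m + seq_len(n)] <- diag(n)
  y0 <- c(x0, as.vector(S0))

  func <- function(t, y, parms) {
    x <- y[seq_len(n)]
    S <- matrix(y[-seq_len(n)], n, nc)
    env <- c(as.list(structure(x, names = model$states)), pv)
    f <- vapply(model$rhs, function(e) as.numeric(eval_num(e, env)), numeric(1))
    evrow <- function(row) vapply(row, function(e)
      as.numeric(eval_num(e, env)), numeric(1))
    Jx <- matrix(unlist(lapply(jac_x, evrow)), nrow = n, byrow = TRUE)
    Jp <- matrix(0, n, nc)
    if (m > 0) {
      Jp[, seq_len(m)] <- matrix(unlist(lapply(jac_p, evrow)),
                                 nrow = n, byrow = TRUE)
    }
    dS <- Jx %*% S + Jp
    list(c(f, as.vector(dS)))
  }
  sol <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    sid_error(sprintf("integration failed near t = %g", sol[nrow(sol), 1]),
              "scalesid_integration_failure")
  }
  x <- sol[, 1 + seq_len(n), drop = FALSE]
  colnames(x) <- model$states
  S <- array(sol[, -(1:(n + 1))], dim = c(length(times), n, nc),
             dimnames = list(NULL, model$states, cols))
  col_values <- c(unlist(pv[pars], use.names = FALSE), unname(x0))
  names(col_values) <- cols
  structure(list(times = times, x = x, S = S, cols = cols,
                 col_values = col_values, model = model,
                 parameter_values = unlist(pv),
                 rtol = rtol, atol = atol, method = "lsoda"),
            class = "sid_traj")
}

#' @export
print.sid_traj <- function(x, ...) {
  cat(sprintf("trajectory with sensitivities: %d time points, states %s, %d sensitivity column(s)\n",
              length(x$times), paste(colnames(x$x), collapse = ", "),
              length(x$cols)))
  invisible(x)
}

#' Stacked elasticity matrix over observed states and time points
#'
#' @param traj a [simulate_with_sensitivities()] result.
#' @param floor_frac entries with `|x_i|` below `floor_frac * max|x_i|` are
#'   masked (`NA`): the elasticity divides by the state value.
#' @return numeric matrix, rows = (observed state, time point), columns as
#'   in `traj$cols`; masked entries are `NA`. Attribute `rows` maps rows
#'   back to state/time.
#' @export
elasticity_matrix <- function(traj, floor_frac = 1e-12) {
  stopifnot(inherits(traj, "sid_traj"))
  model <- traj$model
  obs <- model$observed
  nt <- length(traj$times)
  K <- matrix(NA_real_, length(obs) * nt, length(traj$cols),
              dimnames = list(NULL, traj$cols))
  rows <- data.frame(state = rep(obs, each = nt),
                     time = rep(traj$times, length(obs)))
  r <- 0
  for (s in obs) {
    floor_s <- floor_frac * max(abs(traj$x[, s]), na.rm = TRUE)
    for (ti in seq_len(nt)) {
      r <- r + 1
      xi <- traj$x[ti, s]
      if (!is.finite(xi) || abs(xi) <= floor_s) next
      K[r, ] <- traj$col_values / xi * traj$S[ti, s, ]
    }
  }
  attr(K, "rows") <- rows
  K
}

# map a generator's exponents onto elasticity-matrix columns
.generator_col_coefs <- function(model, generator, cols) {
  a <- generator$exponents
  b <- structure(numeric(length(cols)), names = cols)
  for (p in model$params) if (p %in% names(a)) b[p] <- b[p] + a[[p]]
  lat <- latent_states(model)
  for (s in model$states) {
    icc <- paste0(s, "_0")
    if (s %in% lat) {
      b[icc] <- b[icc] + a[[s]]
    } else {
      ic <- model$init[[s]]
      if (ic$kind == "unknown_parameter" && ic$value %in% names(a)) {
        b[icc] <- b[icc] + a[[ic$value]]
      }
    }
  }
  b
}

#' Check the column dependence of K predicted by each generator
#'
#' A symmetry generator `a` implies that the elasticity columns it couples
#' are linearly dependent: `sum_s a_s K[, s] = 0` along every observed
#' trajectory (IC columns enter through the scaling of latent initial
#' conditions; a zero initial condition contributes a vanishing column). The
#' residual is the maximum over rows of the combination, relative to the row
#' norm.
#'
#' @param K an [elasticity_matrix()].
#' @param model the model the matrix came from.
#' @param generators list of `sid_generator` objects.
#' @return numeric vector, one residual per generator (length 0 when there
#'   are no generators).
#' @export
dependence_check <- function(K, model, generators) {
  vapply(generators, function(g) {
    b <- .generator_col_coefs(model, g, colnames(K))
    res <- 0
    for (r in seq_len(nrow(K))) {
      row <- K[r, ]
      if (any(!is.finite(row))) next
      nrm <- sqrt(sum(row^2))
      if (nrm == 0) next
      res <- max(res, abs(sum(b * row)) / max(nrm, 1))
    }
    res
  }, numeric(1))
}

#' Finite scaling invariance of the observed trajectories
#'
#' Applies the finite scaling `lambda_j -> e^{eps a_j} lambda_j` (and
#' `x_k(0) -> e^{eps a_k} x_k(0)` for latent states) and integrates both the
#' base and the scaled model. For a true symmetry generator the observed
#' trajectories coincide to integration tolerance for every `eps`; for a
#' non-generator the deviation is visible and grows with `|eps|`.
#'
#' @param model a [ode_model()].
#' @param generator a `sid_generator` (or named exponent vector).
#' @param eps scaling magnitude.
#' @param parameter_values base point; defaults to [sid_test_point()].
#' @param times time grid.
#' @param rtol,atol integration tolerances.
#' @return max absolute deviation of the observed states over the grid.
#' @export
finite_invariance_check <- function(model, generator, eps = 0.1,
                                    parameter_values = NULL,
                                    times = seq(0, 1, length.out = 41),
                                    rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(model, "sid_model"))
  if (inherits(generator, "sid_generator")) generator <- generator$exponents
  if (is.null(parameter_values)) parameter_values <- sid_test_point(model)
  pv <- unlist(as.list(parameter_values))

  pv_scaled <- pv
  for (p in names(pv)) {
    if (p %in% names(generator)) {
      pv_scaled[p] <- pv[p] * exp(eps * generator[[p]])
    }
  }
  base <- simulate_model(model, pv, times, rtol, atol)
  # latent initial conditions scale with their state factor
  lat <- latent_states(model)
  ic_override <- NULL
  if (length(lat)) {
    fac <- vapply(lat, function(s)
      if (s %in% names(generator)) exp(eps * generator[[s]]) else 1, numeric(1))
    # avoid double-scaling when the latent IC is an unknown parameter whose
    # scaling factor is tied to the state: rebuild from the unscaled value
    ic_raw <- vapply(lat, .ic_value, numeric(1), model = model,
                     parameter_values = as.list(pv))
    ic_override <- structure(ic_raw * fac, names = lat)
  }
  scaled <- simulate_model(model, pv_scaled, times, rtol, atol,
                           ic_override = ic_override)
  obs <- model$observed
  max(abs(base[, obs, drop = FALSE] - scaled[, obs, drop = FALSE]))
}

#' Choose an integration horizon where the observations move
#'
#' Starting from `t_end`, doubles the horizon (up to `max_factor` times the
#' initial value) until the observed states have changed by at least 10%
#' relative to their scale.
#'
#' @param model a [ode_model()].
#' @param parameter_values named values; defaults to [sid_test_point()].
#' @param t_end initial horizon.
#' @param max_factor cap on the extension.
#' @return a time grid `seq(0, horizon, length.out = 41)`.
#' @export
choose_horizon <- function(model, parameter_values = NULL, t_end = 1,
                           max_factor = 10) {
  if (is.null(parameter_values)) parameter_values <- sid_test_point(model)
  t0 <- t_end
  repeat {
    times <- seq(0, t_end, length.out = 41)
    sol <- simulate_model(model, parameter_values, times,
                          rtol = 1e-8, atol = 1e-10)
    obs <- sol[, model$observed, drop = FALSE]
    scale <- max(abs(obs), 1e-12)
    moved <- max(abs(sweep(obs, 2, obs[1, ]))) / scale
    if (moved >= 0.1 || t_end >= max_factor * t0) return(times)
    t_end <- 2 * t_end
  }
}

#' Export a trajectory's grids as CSV
#'
#' Writes `t`, the states, and the flattened sensitivity and elasticity
#' entries as plain columns.
#'
#' @param traj a [simulate_with_sensitivities()] result.
#' @param path output file.
#' @export
export_trajectory_csv <- function(traj, path) {
  K <- elasticity_matrix(traj)
  rows <- attr(K, "rows")
  df <- data.frame(t = traj$times, traj$x, check.names = FALSE)
  for (s in dimnames(traj$S)[[2]]) {
    for (cn in traj$cols) {
      df[[paste0("S_", s, "_", cn)]] <- traj$S[, s, cn]
    }
  }
  for (cn in traj$cols) {
    for (s in traj$model$observed) {
      df[[paste0("K_", s, "_", cn)]] <- K[rows$state == s, cn]
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
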