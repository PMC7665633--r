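# The scaling-invariance constraint system.
#
# Scale every parameter and every latent state by u = e^w. Invariance of a
# functionally independent summand f(x; lambda) under the scaling family is,
# at first order in the log-scaling factors w_s, the identity
#
#     sum_s a_s * (s * df/ds)  -  [state latent] a_{x_i} * f  ==  0
#
# in the states and parameters, where s runs over the scaled symbols in the
# summand. For monomial summands this reproduces the finite per-summand
# matching exactly; for exponential/rational/trigonometric summands it is
# the derivative of the finite condition at u = 1. Collecting the identity
# over linearly independent functions of (x, lambda) turns each summand into
# exact rational rows of a homogeneous linear system in the w_s.

#' Infinitesimal invariance condition of one summand
#'
#' Returns the coefficient functions c_s(x, lambda) of the linear form
#' `sum_s a_s c_s == 0`: `c_s = s * df/ds` for each scaled symbol in the
#' summand, plus the extra `-f` contribution on the state's own scaling
#' factor when the equation belongs to a latent state.
#'
#' @param summand expression from a certified decomposition.
#' @param model the [ode_model()].
#' @param state name of the state whose equation the summand comes from.
#' @return named list of expressions, names = unknown scaling factors.
#' @export
generator_condition <- function(summand, model, state) {
  latent <- !(state %in% model$observed)
  lat_all <- latent_states(model)
  vars <- all.vars(summand)
  scaled <- c(intersect(model$params, vars), intersect(lat_all, vars))
  coefs <- list()
  for (s in scaled) {
    coefs[[s]] <- canon_expr(call("*", as.name(s), expr_deriv(summand, s)))
  }
  if (latent) {
    extra <- call("-", summand)
    coefs[[state]] <- canon_expr(
      if (is.null(coefs[[state]])) extra else call("+", coefs[[state]], extra))
  }
  coefs
}

# symbolic-collection rows: one exact rational row per independent
# monomial/atom signature appearing across the coefficient functions
.condition_rows_symbolic <- function(coefs, unknowns) {
  per <- lapply(coefs, function(e) terms_collect(expand_terms(e)))
  keys <- unique(unlist(lapply(per, function(ts)
    vapply(ts, function(t) term_key(t$pow), character(1)))))
  rows <- list()
  for (k in keys) {
    num <- numeric(length(unknowns)); den <- rep(1, length(unknowns))
    for (s in names(per)) {
      j <- match(s, unknowns)
      for (t in per[[s]]) {
        if (term_key(t$pow) == k) {
          num[j] <- t$coef$num; den[j] <- t$coef$den
        }
      }
    }
    if (any(num != 0)) rows[[length(rows) + 1]] <- rq(num, den)
  }
  rows
}

# one random exact rational in [1/2, 3/2] with numerator/denominator <= 97
.rq_sample <- function() {
  d <- sample(1:64, 1)
  lo <- ceiling(d / 2); hi <- min(floor(3 * d / 2), 97)
  rq(sample(lo:hi, 1), d)
}

# sampling rows: evaluate the coefficient functions at exact rational points
# (one row per point); falls back to double precision when a summand is not
# rational-evaluable (transcendental pieces)
.condition_rows_sampled <- function(coefs, unknowns, n_rows, retries = 20) {
  rows <- list(); num_rows <- list()
  syms <- unique(unlist(lapply(coefs, all.vars)))
  for (p in seq_len(n_rows)) {
    done <- FALSE
    for (try in seq_len(retries)) {
      env <- lapply(syms, function(s) .rq_sample())
      names(env) <- syms
      vals <- tryCatch(
        lapply(coefs, eval_rq, env = env),
        scalesid_pole = function(c) NULL,
        scalesid_nonrational = function(c) NA,
        scalesid_overflow = function(c) NA)
      if (is.null(vals)) next
      if (length(vals) == 1 && is.na(vals[1])) {
        # transcendental summand: double-precision row
        denv <- lapply(env, rq_num)
        dvals <- vapply(coefs, function(e) as.numeric(eval_num(e, denv)),
                        numeric(1))
        if (!all(is.finite(dvals))) next
        row <- numeric(length(unknowns))
        row[match(names(coefs), unknowns)] <- dvals
        num_rows[[length(num_rows) + 1]] <- row
      } else {
        num <- numeric(length(unknowns)); den <- rep(1, length(unknowns))
        idx <- match(names(coefs), unknowns)
        for (i in seq_along(vals)) {
          num[idx[i]] <- vals[[i]]$num; den[idx[i]] <- vals[[i]]$den
        }
        rows[[length(rows) + 1]] <- rq(num, den)
      }
      done <- TRUE
      break
    }
    if (!done) sid_error("summand evaluates at a pole at all retried sample points",
                         "scalesid_eval_failure")
  }
  list(exact = rows, numeric = num_rows)
}

#' Assemble the scaling constraint system
#'
#' Unknowns are the log-scaling factors: one per parameter, one per latent
#' state, one per unknown initial-condition parameter. Observed states are
#' pinned to scaling 1 and contribute no unknown. Each certified summand
#' contributes constraint rows; initial conditions contribute tie rows
#' (`w_x = w_x0` for an unknown-parameter IC) and pin rows (`w_x = 0` for a
#' known nonzero latent IC). Known-zero ICs contribute nothing.
#'
#' @param model a [ode_model()].
#' @param decomposition a [decompose_model()] result (computed when `NULL`).
#' @param sampling a [sampling_config()]; its seed drives the sampling path.
#' @param method `"symbolic"` (collect the invariance identity over
#'   independent monomials; exact) or `"sampling"` (evaluate the coefficient
#'   functions at exact rational sample points; used as an independent
#'   cross-check of the symbolic path).
#' @return An object of class `sid_system`.
#' @export
assemble_system <- function(model, decomposition = NULL,
                            sampling = sampling_config(),
                            method = c("symbolic", "sampling")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "sid_model"))
  if (is.null(decomposition)) decomposition <- decompose_model(model, sampling)
  lat <- latent_states(model)
  unknowns <- c(model$params, lat, model$ic_params)
  rows <- list(); num_rows <- list(); prov <- list()
  add_rows <- function(rs, state, src) {
    for (r in rs) {
      rows[[length(rows) + 1]] <<- r
      prov[[length(prov) + 1]] <<- list(state = state, source = src)
    }
  }
  n_sample_rows <- length(unknowns) + 5L

  collect <- function() {
    for (s in model$states) {
      eq <- decomposition$equations[[s]]
      for (k in seq_along(eq$summands)) {
        coefs <- generator_condition(eq$summands[[k]], model, s)
        if (length(coefs) == 0) next
        if (method == "symbolic") {
          add_rows(.condition_rows_symbolic(coefs, unknowns), s, k)
        } else {
          got <- .condition_rows_sampled(coefs, unknowns, n_sample_rows)
          add_rows(got$exact, s, k)
          for (r in got$numeric) {
            num_rows[[length(num_rows) + 1]] <<- r
            prov[[length(prov) + 1]] <<- list(state = s, source = k)
          }
        }
      }
    }
  }
  if (method == "sampling") with_seed(sampling$seed, collect()) else collect()

  # initial-condition rows
  unit_row <- function(pairs) { # named coefficients
    num <- numeric(length(unknowns))
    num[match(names(pairs), unknowns)] <- pairs
    rq(num)
  }
  for (s in model$states) {
    ic <- model$init[[s]]
    if (ic$kind == "unknown_parameter") {
      p <- ic$value
      if (s %in% model$observed) {
        add_rows(list(unit_row(structure(1, names = p))), s, "initial_condition")
      } else {
        add_rows(list(unit_row(structure(c(1, -1), names = c(s, p)))),
                 s, "initial_condition")
      }
    } else if (ic$kind == "known_value" && !(s %in% model$observed)) {
      add_rows(list(unit_row(structure(1, names = s))), s, "initial_condition")
    }
  }

  exact <- length(num_rows) == 0
  mat <- rqm_from_rows(rows, length(unknowns))
  numeric_mat <- if (!exact) {
    rbind(rqm_to_double(mat), do.call(rbind, num_rows))
  } else NULL
  structure(list(unknowns = unknowns, matrix = mat, exact = exact,
                 numeric_matrix = numeric_mat, provenance = prov,
                 model = model, method = method,
                 seed = sampling$seed, tol = sampling$tol),
            class = "sid_system")
}

#' @export
print.sid_system <- function(x, ...) {
  cat(sprintf("Scaling constraint system: %d row(s), %d unknown(s) [%s%s]\n",
              if (x$exact) rqm_nrow(x$matrix) else nrow(x$numeric_matrix),
              length(x$unknowns), x$method,
              if (x$exact) ", exact rational" else ", numeric"))
  cat("  unknowns:", paste0("w_", x$unknowns, collapse = ", "), "\n")
  invisible(x)
}

#' Solve for the symmetry generators
#'
#' Computes the nullspace of the constraint matrix. Each basis vector is one
#' symmetry generator: a primitive integer exponent vector `a` (first
#' nonzero entry positive) such that scaling `lambda_j -> e^{eps a_j}
#' lambda_j` and latent `x_k -> e^{eps a_k} x_k` leaves all observed
#' trajectories unchanged for every `eps`. An empty list means only the
#' trivial scaling `u = 1` is admissible.
#'
#' @param system a [assemble_system()] result.
#' @return list of objects of class `sid_generator` (named integer exponent
#'   vectors over the unknowns).
#' @export
solve_generators <- function(system) {
  stopifnot(inherits(system, "sid_system"))
  gens <- if (system$exact) {
    lapply(rqm_nullspace(system$matrix), rq_primitive)
  } else {
    X <- system$numeric_matrix
    nc <- ncol(X)
    if (nrow(X) < nc) X <- rbind(X, matrix(0, nc - nrow(X), nc))
    sv <- svd(X)
    rank <- sum(sv$d > max(system$tol, 1e-10) * max(sv$d, 1))
    if (rank == nc) list() else {
      lapply(seq(rank + 1, nc), function(j) {
        v <- sv$v[, j]
        v <- v / v[which(abs(v) > 1e-8)[1]]
        ints <- lapply(v, function(z) rq_from_double(round(z, 6), max_den = 1000))
        r <- rq(vapply(ints, `[[`, numeric(1), "num"),
                vapply(ints, `[[`, numeric(1), "den"))
        rq_primitive(r)
      })
    }
  }
  gens <- lapply(gens, function(g) {
    structure(list(exponents = structure(as.integer(g), names = system$unknowns)),
              class = "sid_generator")
  })
  gens
}

#' @export
print.sid_generator <- function(x, ...) {
  e <- x$exponents[x$exponents != 0]
  cat("scaling generator:",
      paste(sprintf("a_%s = %d", names(e), e), collapse = ", "), "\n")
  invisible(x)
}

# render one primitive integer exponent row as a monomial relation "... = 1"
.render_monomial <- function(expo, prefix = "u_") {
  nz <- which(expo != 0)
  pos <- nz[expo[nz] > 0]; neg <- nz[expo[nz] < 0]
  fmt <- function(i, e) {
    if (e == 1) paste0(prefix, names(expo)[i])
    else paste0(prefix, names(expo)[i], "^", e)
  }
  lhs <- paste(vapply(pos, function(i) fmt(i, expo[i]), character(1)),
               collapse = " * ")
  if (length(pos) == 0) lhs <- "1"
  for (i in neg) lhs <- paste0(lhs, " / ", fmt(i, -expo[i]))
  paste0(lhs, " = 1")
}

#' Render the identifiability equations
#'
#' Row-reduces the exact constraint matrix and renders every pivot row as a
#' monomial relation `prod u_s^{c_s} = 1` in lowest integer exponents: the
#' human-readable identifiability-equation system of the model.
#'
#' @param system a [assemble_system()] result (symbolic/exact path).
#' @return An object of class `sid_equations`: a list of relations, each with
#'   `exponents` (named integers over the unknowns) and `text`.
#' @export
render_identifiability_equations <- function(system) {
  stopifnot(inherits(system, "sid_system"))
  if (!system$exact) {
    sid_error("identifiability equations require the exact constraint matrix",
              "scalesid_eval_failure")
  }
  if (rqm_nrow(system$matrix) == 0 || length(system$unknowns) == 0) {
    return(structure(list(), class = "sid_equations",
                     unknowns = system$unknowns))
  }
  rr <- rqm_rref(system$matrix)
  eqs <- lapply(seq_along(rr$pivots), function(k) {
    expo <- rq_primitive(rqm_row(rr$mat, k))
    names(expo) <- system$unknowns
    list(exponents = expo, text = .render_monomial(expo))
  })
  structure(eqs, class = "sid_equations", unknowns = system$unknowns)
}

#' @export
print.sid_equations <- function(x, ...) {
  if (length(x) == 0) {
    cat("no scaling constraints\n")
    return(invisible(x))
  }
  cat("Identifiability equations:\n")
  for (eq in x) cat(" ", eq$text, "\n")
  invisible(x)
}
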