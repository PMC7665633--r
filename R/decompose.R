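# Summand decomposition and functional-independence certification.
#
# Each right-hand side is expanded into additive summands. Within one
# equation the summands must be functionally independent along state space
# (no nontrivial constant linear combination vanishes identically); summands
# that fail the test are merged, because the invariance condition of the
# merged sum remains valid even when the per-summand conditions do not split.

#' Sampling configuration for numerical independence tests
#'
#' @param n_points number of sample points; default `3 * n_functions + 5`.
#' @param lower,upper sampling interval for each coordinate (generic positive
#'   points avoid poles and sign cancellations).
#' @param seed RNG seed; part of the certificate.
#' @param tol relative rank tolerance (singular values below `tol * max`
#'   count as zero).
#' @param retries resampling attempts per point when a function evaluates
#'   non-finite (rational right-hand sides can have poles).
#' @param joint if `TRUE`, parameters are resampled at every point alongside
#'   the states; by default they are fixed at one sampled generic value, so
#'   independence is judged as functions of time along trajectories.
#' @export
sampling_config <- function(n_points = NULL, lower = 0.5, upper = 1.5,
                            seed = 0, tol = 1e-9, retries = 20, joint = FALSE) {
  structure(list(n_points = n_points, lower = lower, upper = upper,
                 seed = seed, tol = tol, retries = retries, joint = joint),
            class = "sid_sampling")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split an expression into additive summands
#'
#' Expands to additive normal form; each top-level additive term (sign kept
#' with the term) is one candidate summand. A non-sum is a single summand.
#'
#' @param expr an expression (language object or string).
#' @return list of expressions summing exactly to `expr`.
#' @export
split_summands <- function(expr) {
  if (is.character(expr)) expr <- expr_parse(expr)
  lapply(terms_collect(expand_terms(expr)), term_to_expr)
}

# evaluate a list of expressions at sampled points -> points x functions matrix
.sample_value_matrix <- function(funcs, states, params, sampling, n_points) {
  nf <- length(funcs)
  V <- matrix(NA_real_, n_points, nf)
  runifq <- function(k) stats::runif(k, sampling$lower, sampling$upper)
  par_vals <- structure(runifq(length(params)), names = params)
  for (p in seq_len(n_points)) {
    ok <- FALSE
    for (try in seq_len(sampling$retries)) {
      env <- c(as.list(structure(runifq(length(states)), names = states)),
               if (sampling$joint) as.list(structure(runifq(length(params)),
                                                     names = params))
               else as.list(par_vals))
      vals <- vapply(funcs, function(f) {
        v <- tryCatch(eval_num(f, env), error = function(e) NaN)
        if (length(v) != 1) NaN else as.numeric(v)
      }, numeric(1))
      if (all(is.finite(vals))) {
        V[p, ] <- vals
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      bad <- which(!is.finite(vals))[1]
      sid_error(sprintf("function '%s' evaluates non-finite at all retried points",
                        deparse1(funcs[[bad]])),
                "scalesid_eval_failure")
    }
  }
  V
}

.matrix_rank <- function(V, tol) {
  d <- svd(V, nu = 0, nv = 0)$d
  if (length(d) == 0 || d[1] == 0) return(0L)
  sum(d > tol * d[1])
}

#' Test functional independence of a set of functions
#'
#' Evaluates the functions at sampled generic points of state space
#' (parameters held at fixed sampled constants) and declares the set
#' independent when the numerical rank of the value matrix equals the number
#' of functions. The returned certificate records seed, sample size and
#' tolerance.
#'
#' @param funcs list of expressions (or strings), at least one nonzero.
#' @param states,params character vectors naming the sampled states and the
#'   fixed parameters.
#' @param sampling a [sampling_config()].
#' @return list with `independent` (logical), `rank`, and `certificate`.
#' @export
check_independence <- function(funcs, states, params = character(),
                               sampling = sampling_config()) {
  funcs <- lapply(funcs, function(f) if (is.character(f)) expr_parse(f) else f)
  nf <- length(funcs)
  if (nf == 0) sid_error("need at least one function", "scalesid_eval_failure")
  n_points <- if (is.null(sampling$n_points)) 3L * nf + 5L else sampling$n_points
  V <- with_seed(sampling$seed,
                 .sample_value_matrix(funcs, states, params, sampling, n_points))
  rk <- .matrix_rank(V, sampling$tol)
  list(independent = (rk == nf), rank = rk,
       certificate = list(seed = sampling$seed, n_points = n_points,
                          tol = sampling$tol, rank = rk))
}

# merge groups of mutually dependent columns; returns integer group labels
.dependence_groups <- function(V, tol) {
  nf <- ncol(V)
  parent <- seq_len(nf)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # pairwise proportionality
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    if (.matrix_rank(V[, c(i, j), drop = FALSE], tol) < 2) {
      parent[find(j)] <- find(i)
    }
  }
  groups <- vapply(seq_len(nf), find, integer(1))
  # higher-order dependence: merge a redundant column into the group it
  # projects onto most strongly
  repeat {
    reps <- unique(groups)
    if (length(reps) <= 1) break
    cols <- vapply(reps, function(g) rowSums(V[, groups == g, drop = FALSE]),
                   numeric(nrow(V)))
    rk <- .matrix_rank(cols, tol)
    if (rk == length(reps)) break
    merged <- FALSE
    for (k in seq_along(reps)) {
      others <- cols[, -k, drop = FALSE]
      if (.matrix_rank(others, tol) == rk) {
        cors <- abs(stats::cor(cols[, k], others))
        tgt <- reps[-k][which.max(cors)]
        groups[groups == reps[k]] <- tgt
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  match(groups, unique(groups))
}

#' Decompose a model into functionally independent summands
#'
#' Splits every right-hand side into additive summands, certifies their
#' functional independence numerically, and merges summands that fail the
#' test (recording the merge; constraints from a merged summand are the
#' unsplit invariance condition, which is still valid but blind to additive
#' redistributions inside the merge).
#'
#' @param model a [ode_model()] object.
#' @param sampling a [sampling_config()].
#' @return An object of class `sid_decomposition`: per state a list with
#'   `summands` (expressions), `supports` (states/params of each summand) and
#'   `merged` flags, plus global `merges` and `certificate`.
#' @export
decompose_model <- function(model, sampling = sampling_config()) {
  stopifnot(inherits(model, "sid_model"))
  out <- list()
  merges <- list()
  cert <- NULL
  for (s in model$states) {
    raw <- split_summands(model$rhs[[s]])
    merged_flag <- rep(FALSE, length(raw))
    if (length(raw) > 1) {
      n_points <- if (is.null(sampling$n_points)) 3L * length(raw) + 5L
                  else sampling$n_points
      V <- with_seed(sampling$seed,
                     .sample_value_matrix(raw, model$states, model$params,
                                          sampling, n_points))
      grp <- .dependence_groups(V, sampling$tol)
      if (max(grp) < length(raw)) {
        keep <- list()
        merged_flag <- logical(max(grp))
        for (g in seq_len(max(grp))) {
          members <- which(grp == g)
          if (length(members) == 1) {
            keep[[g]] <- raw[[members]]
          } else {
            comb <- NULL
            for (m in members) comb <- if (is.null(comb)) raw[[m]]
                                       else call("+", comb, raw[[m]])
            keep[[g]] <- canon_expr(comb)
            merged_flag[g] <- TRUE
            merges[[length(merges) + 1]] <-
              list(state = s, members = lapply(raw[members], deparse1),
                   merged = deparse1(keep[[g]]))
          }
        }
        raw <- keep
      }
      cert <- list(seed = sampling$seed, n_points = n_points,
                   tol = sampling$tol)
    }
    supports <- lapply(raw, function(f) {
      v <- all.vars(f)
      list(states = intersect(model$states, v),
           params = intersect(model$params, v))
    })
    out[[s]] <- list(summands = raw, supports = supports, merged = merged_flag)
  }
  structure(list(model = model, equations = out, merges = merges,
                 certificate = cert,
                 sampling = sampling),
            class = "sid_decomposition")
}

#' @export
print.sid_decomposition <- function(x, ...) {
  for (s in names(x$equations)) {
    eq <- x$equations[[s]]
    cat(sprintf("d%s/dt: %d summand(s)\n", s, length(eq$summands)))
    for (k in seq_along(eq$summands)) {
      cat(sprintf("  f_%s%d = %s%s\n", s, k, deparse1(eq$summands[[k]]),
                  if (eq$merged[k]) "   [merged]" else ""))
    }
  }
  if (length(x$merges)) {
    cat(sprintf("%d merge event(s) recorded\n", length(x$merges)))
  }
  invisible(x)
}
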