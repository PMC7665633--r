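# Classification: identifiable parameters, observable latents, groups.

#' Identifiable parameter groups
#'
#' The monomials `prod lambda_j^{c_j}` invariant under every symmetry
#' generator form a lattice: the integer vectors `c` (over parameter
#' coordinates) orthogonal to all generators. This returns a primitive
#' integer basis of that lattice with the trivial single-parameter invariants
#' (identifiable parameters) removed, so each entry is one identifiable
#' group: a combination that can be estimated even though its factors cannot.
#'
#' @param generators list of `sid_generator` objects.
#' @param param_names character vector of parameter coordinates to restrict
#'   to (declared parameters plus IC parameters).
#' @return list of named integer exponent vectors with a `text` attribute.
#' @export
identifiable_groups <- function(generators, param_names) {
  if (length(param_names) == 0) return(list())
  if (length(generators) == 0) return(list())
  G <- do.call(rbind, lapply(generators, function(g)
    unname(g$exponents[param_names])))
  basis <- rqm_nullspace(rqm(G))
  out <- list()
  for (v in basis) {
    expo <- rq_primitive(v)
    names(expo) <- param_names
    if (sum(expo != 0) >= 2) {
      attr(expo, "text") <- .render_monomial(expo, prefix = "")
      out[[length(out) + 1]] <- expo
    }
  }
  out
}

#' Classify parameters and latent states from the symmetry generators
#'
#' A parameter is locally identifiable by this test exactly when its
#' coordinate vanishes in every symmetry generator (its scaling factor is
#' forced to 1); a latent state is observable under the same condition.
#' Parameters whose scaling factors remain coupled form identifiable groups.
#' Positive verdicts mean "no scaling symmetry found": continuous
#' non-scaling symmetries and discrete symmetries (fixed scaling values
#' different from 1) are outside the reach of the test and are flagged as a
#' standing caveat.
#'
#' @param model a [ode_model()].
#' @param generators list from [solve_generators()].
#' @param equations optional [render_identifiability_equations()] result.
#' @param system optional [assemble_system()] result (provenance).
#' @param decomposition optional [decompose_model()] result (merge caveats).
#' @return An object of class `sid_report`.
#' @export
classify <- function(model, generators, equations = NULL, system = NULL,
                     decomposition = NULL) {
  stopifnot(inherits(model, "sid_model"))
  pars <- c(model$params, model$ic_params)
  lat <- latent_states(model)
  coord <- function(name) vapply(generators, function(g)
    as.numeric(g$exponents[[name]]), numeric(1))
  par_verdict <- vapply(pars, function(p) {
    if (length(generators) == 0 || all(coord(p) == 0)) "identifiable"
    else "unidentifiable"
  }, character(1))
  lat_verdict <- vapply(lat, function(s) {
    if (length(generators) == 0 || all(coord(s) == 0)) "observable"
    else "unobservable"
  }, character(1))

  caveats <- character(0)
  used <- unique(unlist(c(lapply(model$rhs, all.vars),
                          lapply(model$init, function(ic)
                            if (ic$kind == "unknown_parameter") ic$value))))
  absent <- setdiff(model$params, used)
  for (p in absent) {
    par_verdict[[p]] <- "unidentifiable"
    caveats <- c(caveats, sprintf(
      "parameter '%s' appears in no equation (structurally absent)", p))
  }
  if (!is.null(decomposition) && length(decomposition$merges)) {
    for (m in decomposition$merges) {
      caveats <- c(caveats, sprintf(
        "d%s/dt: dependent summands merged into '%s'; additive redistributions inside the merge are invisible to scaling (scaling-blind)",
        m$state, m$merged))
    }
  }
  obs_ic_kinds <- vapply(model$observed, function(s) model$init[[s]]$kind,
                         character(1))
  caveats <- c(caveats,
    "verdicts are local and scaling-based: discrete symmetries and fixed scaling values != 1 are not detected",
    sprintf("observed-state initial conditions accepted as declared (%s)",
            paste(sprintf("%s: %s", model$observed, obs_ic_kinds),
                  collapse = ", ")))

  structure(list(model = model,
                 parameters = par_verdict,
                 latents = lat_verdict,
                 equations = equations,
                 groups = identifiable_groups(generators, pars),
                 generators = generators,
                 caveats = caveats,
                 provenance = list(
                   method = if (is.null(system)) NA_character_ else system$method,
                   seed = if (is.null(system)) NA_integer_ else system$seed,
                   tol = if (is.null(system)) NA_real_ else system$tol,
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "sid_report")
}

#' Run the full identifiability analysis
#'
#' Decomposes the right-hand sides into functionally independent summands,
#' assembles the homogeneous linear system in the log-scaling factors,
#' solves for the symmetry generators and classifies every parameter and
#' latent state.
#'
#' @param model a [ode_model()] object (or model document accepted by
#'   [parse_model()]).
#' @param sampling a [sampling_config()].
#' @param method constraint assembly path, see [assemble_system()].
#' @return An object of class `sid_report`.
#' @examples
#' m <- ode_model(states = "x", params = c("lambda1", "lambda2"),
#'                rhs = c(x = "-lambda1*lambda2*x"), observed = "x",
#'                init = list(x = "x0"))
#' check_identifiability(m)
#' @export
check_identifiability <- function(model, sampling = sampling_config(),
                                  method = "symbolic") {
  if (is.character(model)) model <- parse_model(model)
  dec <- decompose_model(model, sampling)
  sys <- assemble_system(model, dec, sampling, method = method)
  gens <- solve_generators(sys)
  eqs <- if (sys$exact) render_identifiability_equations(sys) else NULL
  classify(model, gens, equations = eqs, system = sys, decomposition = dec)
}

#' Re-run the analysis with additional observed states
#'
#' Answers the experiment-design question "which latent states should be
#' measured": observing a latent state pins its scaling factor to 1 and can
#' decouple identifiable groups.
#'
#' @param model a [ode_model()].
#' @param extra_observed character vector of latent states to observe.
#' @param ... passed to [check_identifiability()].
#' @return An object of class `sid_report` for the augmented model.
#' @export
what_if_observed <- function(model, extra_observed, ...) {
  stopifnot(inherits(model, "sid_model"))
  extra_observed <- as.character(extra_observed)
  bad <- setdiff(extra_observed, latent_states(model))
  if (length(bad)) {
    sid_error(sprintf("'%s' is not a latent state", bad[1]),
              "scalesid_bad_observed")
  }
  m2 <- model
  m2$observed <- m2$states[m2$states %in% c(model$observed, extra_observed)]
  check_identifiability(m2, ...)
}

#' @export
print.sid_report <- function(x, ...) {
  if (!is.null(x$equations)) print(x$equations)
  n_gen <- length(x$generators)
  if (n_gen == 0) {
    cat("Only the trivial scaling u = 1 is admissible.\n")
  } else {
    cat(sprintf("%d nontrivial scaling symmetry generator(s) found.\n", n_gen))
  }
  cat("Parameters:\n")
  for (p in names(x$parameters)) {
    cat(sprintf("  %-12s %s\n", p, x$parameters[[p]]))
  }
  if (length(x$latents)) {
    cat("Latent states:\n")
    for (s in names(x$latents)) {
      cat(sprintf("  %-12s %s\n", s, x$latents[[s]]))
    }
  }
  if (length(x$groups)) {
    cat("Identifiable groups:\n")
    for (g in x$groups) cat("  ", sub(" = 1$", "", attr(g, "text")), "\n")
  }
  invisible(x)
}

#' Serialize a report to JSON (schema "scalesid-report/1")
#'
#' Exponent vectors are emitted as integer strings so the exact values
#' survive any JSON number handling downstream.
#'
#' @param report a `sid_report`.
#' @param path optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
report_to_json <- function(report, path = NULL) {
  expo_map <- function(e) {
    nz <- which(e != 0)
    stats::setNames(as.list(sprintf("%d", e[nz])), names(e)[nz])
  }
  doc <- list(
    schema = "scalesid-report/1",
    parameters = as.list(report$parameters),
    latents = as.list(report$latents),
    identifiability_equations = lapply(
      if (is.null(report$equations)) list() else report$equations,
      function(eq) list(exponents = expo_map(eq$exponents), text = eq$text)),
    groups = lapply(report$groups, function(g)
      list(exponents = expo_map(g), text = attr(g, "text"))),
    generators = lapply(report$generators, function(g) expo_map(g$exponents)),
    caveats = report$caveats,
    provenance = report$provenance)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
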