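# Model declaration, parsing and validation.

#' Declare an initial condition
#'
#' @param value `0` (known to be zero), a finite number (known value), or a
#'   character string naming an initial-condition parameter (unknown value to
#'   be estimated).
#' @return An object of class `sid_ic` with fields `kind` (one of
#'   `"known_zero"`, `"known_value"`, `"unknown_parameter"`) and `value`.
#' @export
initial_condition <- function(value) {
  if (inherits(value, "sid_ic")) return(value)
  if (is.character(value) && length(value) == 1) {
    v <- expr_parse(value)
    if (is.name(v)) {
      return(structure(list(kind = "unknown_parameter", value = as.character(v)),
                       class = "sid_ic"))
    }
    if (length(all.vars(v)) == 0) value <- eval(v, baseenv())
    else sid_error(sprintf("initial condition '%s' is neither a number nor a parameter name",
                           value), "scalesid_parse_error")
  }
  if (is.numeric(value) && length(value) == 1) {
    if (!is.finite(value)) sid_error("initial condition must be finite",
                                     "scalesid_parse_error")
    kind <- if (value == 0) "known_zero" else "known_value"
    return(structure(list(kind = kind, value = value), class = "sid_ic"))
  }
  sid_error("invalid initial condition", "scalesid_parse_error")
}

#' Declare an ODE model
#'
#' An autonomous ODE system dx_i/dt = f_i(x; lambda) together with the subset
#' of states that are experimentally observed and a declaration of each
#' initial condition. Right-hand sides are parsed from infix strings over the
#' declared symbols with operators `+ - * / ^` and the functions
#' `exp`, `log`, `sin`, `cos`, `tan`; rational constants such as `1/2` are
#' kept exact. Expressions are stored in a canonical expanded form.
#'
#' Initial conditions may be known to be zero, known nonzero values, or
#' unknown parameters. An unknown initial-condition symbol that is not in
#' `params` is registered as an additional analysis parameter (it receives an
#' identifiability verdict but does not count towards `m`, the number of
#' kinetic parameters).
#'
#' @param states character vector of state names (declaration order is kept).
#' @param params character vector of parameter names.
#' @param rhs named character vector or list (names = states) of right-hand
#'   side expressions.
#' @param observed character vector, non-empty subset of `states`.
#' @param init named list (names = states) of initial conditions, each as
#'   accepted by [initial_condition()]. States omitted from `init` default to
#'   known-zero.
#' @return An object of class `sid_model`.
#' @examples
#' m <- ode_model(
#'   states = "x", params = c("lambda1", "lambda2"),
#'   rhs = c(x = "-lambda1*lambda2*x"), observed = "x",
#'   init = list(x = "x0"))
#' latent_states(m)
#' @export
ode_model <- function(states, params, rhs, observed, init = NULL) {
  states <- as.character(states); params <- as.character(params)
  observed <- as.character(observed)
  if (length(states) < 1) sid_error("need at least one state", "scalesid_parse_error")
  if (length(params) < 1) sid_error("need at least one parameter", "scalesid_parse_error")

  if (is.null(init)) init <- list()
  init <- lapply(init, initial_condition)
  for (s in setdiff(states, names(init))) init[[s]] <- initial_condition(0)
  if (!all(names(init) %in% states)) {
    sid_error(sprintf("initial condition given for non-state '%s'",
                      setdiff(names(init), states)[1]), "scalesid_bad_observed")
  }
  init <- init[states]

  ic_params <- unique(unlist(lapply(init, function(ic) {
    if (ic$kind == "unknown_parameter" && !(ic$value %in% params)) ic$value
  })))
  ic_params <- as.character(ic_params[!vapply(ic_params, is.null, logical(1))])

  all_names <- c(states, params, ic_params)
  if (anyDuplicated(all_names)) {
    sid_error(sprintf("duplicate name '%s' among states/parameters",
                      all_names[duplicated(all_names)][1]),
              "scalesid_duplicate_name")
  }
  if (length(observed) == 0 || !all(observed %in% states)) {
    bad <- setdiff(observed, states)
    sid_error(if (length(bad)) sprintf("observed name '%s' is not a state", bad[1])
              else "observed set must be non-empty",
              "scalesid_bad_observed")
  }
  observed <- states[states %in% observed]

  if (is.character(rhs)) rhs <- as.list(rhs)
  if (is.null(names(rhs)) || !setequal(names(rhs), states)) {
    sid_error("rhs must be named by the states, one expression per state",
              "scalesid_parse_error")
  }
  declared <- c(states, params)
  rhs <- lapply(states, function(s) {
    e <- rhs[[s]]
    if (is.character(e)) e <- expr_parse(e)
    expr_validate(e, declared, where = sprintf("d%s/dt", s))
    canon_expr(e)
  })
  names(rhs) <- states

  structure(list(states = states, params = params, rhs = rhs,
                 observed = observed, init = init, ic_params = ic_params),
            class = "sid_model")
}

#' Latent (unobserved) states of a model
#'
#' @param model a [ode_model()] object.
#' @return character vector of unobserved states in declaration order
#'   (empty when all states are observed).
#' @export
latent_states <- function(model) {
  stopifnot(inherits(model, "sid_model"))
  setdiff(model$states, model$observed)
}

#' @export
print.sid_model <- function(x, ...) {
  cat(sprintf("ODE model: %d state(s), %d parameter(s)\n",
              length(x$states), length(x$params)))
  for (s in x$states) {
    cat(sprintf("  d%s/dt = %s\n", s, deparse1(x$rhs[[s]])))
  }
  for (s in x$states) {
    ic <- x$init[[s]]
    v <- switch(ic$kind, known_zero = "0", known_value = format(ic$value),
                unknown_parameter = paste0(ic$value, " (unknown)"))
    cat(sprintf("  %s(0) = %s\n", s, v))
  }
  cat("  observed:", paste(x$observed, collapse = ", "), "\n")
  lat <- latent_states(x)
  if (length(lat)) cat("  latent:  ", paste(lat, collapse = ", "), "\n")
  invisible(x)
}

# ---- document format --------------------------------------------------------

#' Parse a model document
#'
#' Reads a YAML (or JSON) model document with keys `states`, `params`,
#' `odes` (map state -> expression string), `observed` (list of states) and
#' `init` (map state -> 0 | number | parameter name). `text` may be a file
#' path or the document itself.
#'
#' @param text path to a model file, or a character scalar holding the
#'   document.
#' @return A validated [ode_model()] object.
#' @export
parse_model <- function(text) {
  doc <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    yaml::read_yaml(text)
  } else {
    yaml::yaml.load(paste(text, collapse = "\n"))
  }
  if (!is.list(doc)) sid_error("model document is not a mapping", "scalesid_parse_error")
  need <- c("states", "params", "odes", "observed")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    sid_error(sprintf("model document lacks section(s): %s",
                      paste(miss, collapse = ", ")), "scalesid_parse_error")
  }
  init <- doc$init
  if (!is.null(init)) init <- lapply(init, function(v) initial_condition(v))
  ode_model(states = unlist(doc$states), params = unlist(doc$params),
            rhs = lapply(doc$odes, function(e) as.character(e)),
            observed = unlist(doc$observed), init = init)
}

#' Render a model back into a YAML document
#'
#' `parse_model(render_model(m))` round-trips to a structurally equal model.
#'
#' @param model a [ode_model()] object.
#' @return character scalar holding a YAML model document.
#' @export
render_model <- function(model) {
  stopifnot(inherits(model, "sid_model"))
  init <- lapply(model$init, function(ic) {
    switch(ic$kind, known_zero = 0, known_value = ic$value,
           unknown_parameter = ic$value)
  })
  doc <- list(states = as.list(model$states),
              params = as.list(model$params),
              odes = lapply(model$rhs, deparse1),
              observed = as.list(model$observed),
              init = init)
  yaml::as.yaml(doc)
}

#' SBML import hook
#'
#' Placeholder entry point for importing SBML kinetic laws as a model
#' document. No SBML/MathML reader is bundled with this package, so the hook
#' reports a clean, catchable failure instead of attempting a partial parse.
#'
#' @param path path to an SBML file.
#' @export
import_sbml <- function(path) {
  sid_error(paste0("SBML import is not available in this build; ",
                   "convert the kinetic laws to a YAML model document instead"),
            "scalesid_sbml_unavailable")
}
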