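# Built-in fixture models with expected verdicts for regression testing.

.catalogue <- function() {
  list(
    death = list(
      note = "one-state death model, rate = product of two parameters; only the product is estimable",
      asserted = TRUE,
      build = function() ode_model(
        states = "x",
        params = c("lambda1", "lambda2"),
        rhs = c(x = "-lambda1*lambda2*x"),
        observed = "x",
        init = list(x = "x0")),
      expected = list(
        parameters = c(lambda1 = "unidentifiable", lambda2 = "unidentifiable",
                       x0 = "identifiable"),
        latents = character(0),
        groups = list(c(lambda1 = 1L, lambda2 = 1L)))),
    death_immigration = list(
      note = "death model with constant immigration; both rates identifiable",
      asserted = TRUE,
      build = function() ode_model(
        states = "x",
        params = c("lambda1", "lambda2"),
        rhs = c(x = "lambda1 - lambda2*x"),
        observed = "x",
        init = list(x = "x0")),
      expected = list(
        parameters = c(lambda1 = "identifiable", lambda2 = "identifiable",
                       x0 = "identifiable"),
        latents = character(0),
        groups = list())),
    twostate_nonlinear = list(
      note = "two-state quadratic model, x1 observed; the latent x2 can be rescaled freely against lambda2 and lambda3",
      asserted = TRUE,
      build = function() ode_model(
        states = c("x1", "x2"),
        params = c("lambda1", "lambda2", "lambda3", "lambda4"),
        rhs = c(x1 = "lambda1*x1^2 + lambda2*x1*x2",
                x2 = "lambda3*x1^2 + lambda4*x1*x2"),
        observed = "x1",
        init = list(x1 = 0, x2 = 0)),
      expected = list(
        parameters = c(lambda1 = "identifiable", lambda2 = "unidentifiable",
                       lambda3 = "unidentifiable", lambda4 = "identifiable"),
        latents = c(x2 = "unobservable"),
        groups = list(c(lambda1 = 0L, lambda2 = 1L, lambda3 = 1L,
                        lambda4 = 0L)))),
    goodwin = list(
      note = paste("three-state Goodwin oscillator with a Hill-type feedback,",
                   "x1 observed; reconstructed standard form, no asserted verdict",
                   "(form-dependent)"),
      asserted = FALSE,
      build = function() ode_model(
        states = c("x1", "x2", "x3"),
        params = c("a", "A", "b", "alpha", "beta", "gamma", "delta"),
        rhs = c(x1 = "a/(A + x3^10) - b*x1",
                x2 = "alpha*x1 - beta*x2",
                x3 = "gamma*x2 - delta*x3"),
        observed = "x1",
        init = list(x1 = 0.1, x2 = 0.2, x3 = 2.5)),
      expected = NULL))
}

#' List the built-in catalogue models
#'
#' @return data.frame with columns `name`, `asserted`, `note`.
#' @export
catalogue_models <- function() {
  cat_ <- .catalogue()
  data.frame(name = names(cat_),
             asserted = vapply(cat_, `[[`, logical(1), "asserted"),
             note = vapply(cat_, `[[`, character(1), "note"),
             row.names = NULL)
}

.catalogue_entry <- function(name) {
  cat_ <- .catalogue()
  if (!(name %in% names(cat_))) {
    sid_error(sprintf("unknown catalogue model '%s'; available: %s",
                      name, paste(names(cat_), collapse = ", ")),
              "scalesid_unknown_model")
  }
  cat_[[name]]
}

#' Fetch a built-in model
#'
#' @param name catalogue entry name (see [catalogue_models()]).
#' @return a freshly built, validated [ode_model()].
#' @export
get_model <- function(name) .catalogue_entry(name)$build()

#' Expected identifiability verdict of a catalogue model
#'
#' Only main-text-definable models carry asserted verdicts; for
#' reconstructed fixtures (e.g. `goodwin`) this returns `NULL`.
#'
#' @param name catalogue entry name.
#' @return list with `parameters`, `latents`, `groups`, or `NULL`.
#' @export
expected_verdict <- function(name) .catalogue_entry(name)$expected
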