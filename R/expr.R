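# Expression handling on base-R parse trees.
#
# The grammar is deliberately small: + - * / ^ parentheses, the functions
# exp, log, sin, cos, tan, numeric constants (rationals kept exact) and
# declared symbols. Expressions are expanded into additive normal form where
# a *term* is an exact-rational coefficient times a power product over
# "keys"; a key is either a declared symbol or an opaque atom (a
# canonicalized sub-expression such as exp(lambda*x) or a polynomial
# denominator) that the expansion does not look into.

.SCALESID_FUNS <- c("exp", "log", "sin", "cos", "tan")
.SCALESID_OPS <- c("+", "-", "*", "/", "^", "(")

sid_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "scalesid_error")))
}

#' Parse a single infix expression string.
#' @noRd
expr_parse <- function(text) {
  e <- tryCatch(str2lang(text), error = function(err) {
    sid_error(sprintf("cannot parse expression '%s': %s", text,
                      conditionMessage(err)),
              "scalesid_parse_error")
  })
  if (is.character(e)) {
    sid_error(sprintf("expression '%s' is a string, not a formula", text),
              "scalesid_parse_error")
  }
  e
}

#' Validate an expression against the grammar and the declared symbols.
#' @noRd
expr_validate <- function(e, declared, where = "expression") {
  walk <- function(x) {
    if (is.numeric(x)) {
      if (!is.finite(x)) {
        sid_error(sprintf("non-finite constant in %s", where),
                  "scalesid_parse_error")
      }
      return(invisible())
    }
    if (is.name(x)) {
      nm <- as.character(x)
      if (!(nm %in% declared)) {
        sid_error(sprintf("undeclared symbol '%s' in %s", nm, where),
                  "scalesid_undeclared_symbol", symbol = nm)
      }
      return(invisible())
    }
    if (is.call(x)) {
      fn <- as.character(x[[1]])
      if (!(fn %in% c(.SCALESID_OPS, .SCALESID_FUNS))) {
        sid_error(sprintf("function '%s' is not in the model grammar (%s)",
                          fn, where),
                  "scalesid_bad_function", fn = fn)
      }
      for (i in seq_along(x)[-1]) walk(x[[i]])
      return(invisible())
    }
    sid_error(sprintf("unsupported element of class '%s' in %s",
                      class(x)[1], where), "scalesid_parse_error")
  }
  walk(e)
  invisible(e)
}

# ---- additive normal form ---------------------------------------------------

.term <- function(coef, pow = numeric(0)) list(coef = coef, pow = pow)

.pow_merge <- function(a, b) {
  p <- c(a, b)
  if (anyDuplicated(names(p))) p <- tapply(p, names(p), sum)[unique(names(p))]
  p <- p[p != 0]
  if (length(p)) p[order(names(p))] else numeric(0)
}

.term_mul <- function(a, b) .term(rq_mul(a$coef, b$coef), .pow_merge(a$pow, b$pow))
.term_neg <- function(a) .term(rq_neg(a$coef), a$pow)
.terms_neg <- function(ts) lapply(ts, .term_neg)
.term_inv <- function(a) .term(rq_div(rq(1), a$coef), -a$pow)

term_key <- function(pow) {
  if (length(pow) == 0) return("")
  paste(sprintf("%s^%.12g", names(pow), unname(pow)), collapse = "*")
}

#' Merge terms with identical power products; drop exact zeros.
#' @noRd
terms_collect <- function(ts) {
  if (length(ts) == 0) return(list())
  keys <- vapply(ts, function(t) term_key(t$pow), character(1))
  out <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    coef <- Reduce(rq_add, lapply(ts[idx], `[[`, "coef"))
    if (!rq_is_zero(coef)) out[[length(out) + 1]] <- .term(coef, ts[[idx[1]]]$pow)
  }
  keys2 <- vapply(out, function(t) term_key(t$pow), character(1))
  out[order(keys2)]
}

.atom_term <- function(e, expo = 1) {
  key <- deparse1(canon_expr(e))
  .term(rq(1), structure(expo, names = key))
}

#' Expand an expression into a list of additive terms.
#' @noRd
expand_terms <- function(e) {
  if (is.numeric(e)) return(list(.term(rq_from_double(e))))
  if (is.name(e)) return(list(.term(rq(1), structure(1, names = as.character(e)))))
  if (!is.call(e)) sid_error("unsupported expression element", "scalesid_parse_error")
  fn <- as.character(e[[1]])
  if (fn == "(") return(expand_terms(e[[2]]))
  if (fn == "+") {
    if (length(e) == 2) return(expand_terms(e[[2]]))
    return(c(expand_terms(e[[2]]), expand_terms(e[[3]])))
  }
  if (fn == "-") {
    if (length(e) == 2) return(.terms_neg(expand_terms(e[[2]])))
    return(c(expand_terms(e[[2]]), .terms_neg(expand_terms(e[[3]]))))
  }
  if (fn == "*") {
    ta <- expand_terms(e[[2]]); tb <- expand_terms(e[[3]])
    out <- list()
    for (a in ta) for (b in tb) out[[length(out) + 1]] <- .term_mul(a, b)
    return(out)
  }
  if (fn == "/") {
    ta <- expand_terms(e[[2]])
    tb <- terms_collect(expand_terms(e[[3]]))
    if (length(tb) == 0) sid_error("division by expression that is identically zero",
                                   "scalesid_parse_error")
    inv <- if (length(tb) == 1) .term_inv(tb[[1]]) else .atom_term(e[[3]], -1)
    return(lapply(ta, .term_mul, b = inv))
  }
  if (fn == "^") {
    expo_e <- e[[3]]
    if (length(all.vars(expo_e)) == 0) {
      expo <- eval(expo_e, baseenv())
      base_terms <- terms_collect(expand_terms(e[[2]]))
      if (length(base_terms) == 0) {
        if (expo <= 0) sid_error("0 raised to a non-positive power",
                                 "scalesid_parse_error")
        return(list())
      }
      if (expo == round(expo)) {
        if (length(base_terms) == 1) {
          t1 <- base_terms[[1]]
          return(list(.term(rq_pow(t1$coef, expo), {
            p <- t1$pow * expo; p[p != 0]
          })))
        }
        if (expo >= 0 && expo <= 16) {
          acc <- list(.term(rq(1)))
          for (i in seq_len(expo)) {
            nxt <- list()
            for (a in acc) for (b in base_terms) nxt[[length(nxt) + 1]] <- .term_mul(a, b)
            acc <- terms_collect(nxt)
          }
          return(acc)
        }
        return(list(.atom_term(e[[2]], expo)))
      }
      # fractional exponent: only split a unit-coefficient power product
      if (length(base_terms) == 1 && rq_eq(base_terms[[1]]$coef, rq(1))) {
        p <- base_terms[[1]]$pow * expo
        return(list(.term(rq(1), p[p != 0])))
      }
      return(list(.atom_term(e[[2]], expo)))
    }
    # symbolic exponent: opaque atom
    key <- call("^", canon_expr(e[[2]]), canon_expr(expo_e))
    return(list(.term(rq(1), structure(1, names = deparse1(key)))))
  }
  if (fn %in% .SCALESID_FUNS) {
    key <- as.call(list(as.name(fn), canon_expr(e[[2]])))
    return(list(.term(rq(1), structure(1, names = deparse1(key)))))
  }
  sid_error(sprintf("function '%s' is not in the model grammar", fn),
            "scalesid_bad_function", fn = fn)
}

# ---- rebuilding expressions -------------------------------------------------

.coef_expr <- function(coef) {
  if (coef$den == 1) return(coef$num)
  call("/", coef$num, coef$den)
}

term_to_expr <- function(t) {
  factors <- list()
  for (i in seq_along(t$pow)) {
    base <- str2lang(names(t$pow)[i])
    e <- unname(t$pow[i])
    factors[[i]] <- if (e == 1) base else call("^", base, e)
  }
  prod_e <- NULL
  for (f in factors) prod_e <- if (is.null(prod_e)) f else call("*", prod_e, f)
  coef <- t$coef
  if (is.null(prod_e)) return(.coef_expr(coef))
  if (rq_eq(coef, rq(1))) return(prod_e)
  if (rq_eq(coef, rq(-1))) return(call("-", prod_e))
  call("*", .coef_expr(coef), prod_e)
}

terms_to_expr <- function(ts) {
  if (length(ts) == 0) return(0)
  out <- NULL
  for (t in ts) {
    te <- term_to_expr(t)
    if (is.null(out)) {
      out <- te
    } else if (is.call(te) && identical(te[[1]], as.name("-")) && length(te) == 2) {
      out <- call("-", out, te[[2]])
    } else if (rq_num(t$coef) < 0) {
      out <- call("-", out, term_to_expr(.term_neg(t)))
    } else {
      out <- call("+", out, te)
    }
  }
  out
}

#' Canonical form: expanded, collected, terms in sorted key order.
#' @noRd
canon_expr <- function(e) terms_to_expr(terms_collect(expand_terms(e)))

#' Does the expression simplify exactly to zero?
#' @noRd
expr_is_zero <- function(e) length(terms_collect(expand_terms(e))) == 0

#' Symbolic partial derivative (base R D()).
#' @noRd
expr_deriv <- function(e, name) stats::D(e, name)

#' Numeric evaluation at a named list/vector of values.
#' @noRd
eval_num <- function(e, values) eval(e, as.list(values))

# ---- exact rational evaluation ---------------------------------------------

#' Evaluate an expression exactly at rational points. Signals condition class
#' "scalesid_nonrational" when the expression involves transcendental
#' functions or non-integer powers, and "scalesid_pole" on division by zero.
#' @param env named list of scalar rationals (rq)
#' @noRd
eval_rq <- function(e, env) {
  if (is.numeric(e)) return(rq_from_double(e))
  if (is.name(e)) {
    nm <- as.character(e)
    v <- env[[nm]]
    if (is.null(v)) sid_error(sprintf("no value for symbol '%s'", nm),
                              "scalesid_eval_error")
    return(v)
  }
  fn <- as.character(e[[1]])
  if (fn == "(") return(eval_rq(e[[2]], env))
  if (fn == "+") {
    if (length(e) == 2) return(eval_rq(e[[2]], env))
    return(rq_add(eval_rq(e[[2]], env), eval_rq(e[[3]], env)))
  }
  if (fn == "-") {
    if (length(e) == 2) return(rq_neg(eval_rq(e[[2]], env)))
    return(rq_sub(eval_rq(e[[2]], env), eval_rq(e[[3]], env)))
  }
  if (fn == "*") return(rq_mul(eval_rq(e[[2]], env), eval_rq(e[[3]], env)))
  if (fn == "/") {
    den <- eval_rq(e[[3]], env)
    if (rq_is_zero(den)) sid_error("pole at sample point", "scalesid_pole")
    return(rq_div(eval_rq(e[[2]], env), den))
  }
  if (fn == "^") {
    if (length(all.vars(e[[3]])) > 0) {
      sid_error("symbolic exponent is not rational-evaluable", "scalesid_nonrational")
    }
    expo <- eval(e[[3]], baseenv())
    if (expo != round(expo)) {
      sid_error("fractional power is not rational-evaluable", "scalesid_nonrational")
    }
    base <- eval_rq(e[[2]], env)
    if (expo < 0 && rq_is_zero(base)) sid_error("pole at sample point", "scalesid_pole")
    return(rq_pow(base, expo))
  }
  sid_error(sprintf("function '%s' is not rational-evaluable", fn),
            "scalesid_nonrational")
}
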