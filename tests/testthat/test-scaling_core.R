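eq_texts <- function(report_or_eqs) {
  eqs <- if (inherits(report_or_eqs, "sid_report")) report_or_eqs$equations
         else report_or_eqs
  sort(vapply(eqs, `[[`, character(1), "text"))
}

test_that("per-summand invariance conditions match hand derivations", {
  m <- parse_model(death_doc())
  co <- generator_condition(m$rhs$x, m, "x")
  expect_setequal(names(co), c("lambda1", "lambda2"))
  # both coefficient functions are -lambda1*lambda2*x, so one constraint
  expect_identical(deparse1(co$lambda1), deparse1(co$lambda2))

  # constant summand in an observed equation pins its parameter
  mi <- get_model("death_immigration")
  dec <- decompose_model(mi)
  sums <- dec$equations$x$summands
  const <- sums[[which(vapply(sums, function(f)
    identical(all.vars(f), "lambda1"), logical(1)))]]
  co2 <- generator_condition(const, mi, "x")
  expect_equal(names(co2), "lambda1")
  expect_identical(deparse1(co2$lambda1), "lambda1")

  # latent equation: lambda3*x1^2 gets the -f contribution on x2
  mt <- parse_model(twostate_doc())
  co3 <- generator_condition(str2lang("lambda3*x1^2"), mt, "x2")
  expect_setequal(names(co3), c("lambda3", "x2"))
  s <- call("+", co3$lambda3, co3$x2)
  expect_true(scalesid:::expr_is_zero(s))

  # exponential with a latent state inside the exponent
  me <- exp_latent_model()
  co4 <- generator_condition(str2lang("exp(lambda*x2)"), me, "x1")
  expect_setequal(names(co4), c("lambda", "x2"))
  # oracle: both coefficients are lambda*x2*exp(lambda*x2); the difference
  # must vanish identically (checked symbolically and at sample points)
  expect_true(scalesid:::expr_is_zero(call("-", co4$lambda, co4$x2)))
  env <- list(lambda = 0.7, x2 = 1.3)
  expect_equal(eval(co4$lambda, env), 0.7 * 1.3 * exp(0.7 * 1.3))
})

test_that("assembled systems reproduce the worked identifiability equations", {
  rd <- check_identifiability(parse_model(death_doc()))
  expect_equal(eq_texts(rd),
               sort(c("u_lambda1 * u_lambda2 = 1", "u_x0 = 1")))

  rt <- check_identifiability(parse_model(twostate_doc()))
  expect_equal(eq_texts(rt),
               sort(c("u_lambda1 = 1", "u_lambda2 * u_x2 = 1",
                      "u_lambda3 / u_x2 = 1", "u_lambda4 = 1")))

  ri <- check_identifiability(get_model("death_immigration"))
  expect_length(ri$generators, 0)
  expect_equal(eq_texts(ri),
               sort(c("u_lambda1 = 1", "u_lambda2 = 1", "u_x0 = 1")))
})

test_that("solve_generators finds the expected nullspace bases", {
  sysd <- assemble_system(parse_model(death_doc()))
  expect_equal(sysd$unknowns, c("lambda1", "lambda2", "x0"))
  gd <- solve_generators(sysd)
  expect_length(gd, 1)
  expect_equal(unname(expo_sorted(gd[[1]])[c("lambda1", "lambda2", "x0")]),
               c(1L, -1L, 0L))

  gt <- solve_generators(assemble_system(parse_model(twostate_doc())))
  expect_length(gt, 1)
  e <- expo_sorted(gt[[1]])
  expect_equal(unname(e[c("lambda1", "lambda4")]), c(0L, 0L))
  expect_equal(abs(unname(e[c("lambda2", "lambda3", "x2")])), c(1L, 1L, 1L))
  expect_equal(e[["lambda2"]] * e[["lambda3"]], -1L)  # opposite signs
  expect_equal(e[["lambda3"]], e[["x2"]])             # u_lambda3 = u_x2
})

test_that("a model with all states observed has parameter-only unknowns", {
  m <- ode_model(states = c("x1", "x2"), params = c("a", "b"),
                 rhs = c(x1 = "a*x1", x2 = "b*x1*x2"),
                 observed = c("x1", "x2"))
  sys <- assemble_system(m)
  expect_equal(sys$unknowns, c("a", "b"))
  expect_length(solve_generators(sys), 0)
})

test_that("an unused parameter yields a free generator and no equations rows", {
  m <- ode_model(states = "x", params = c("k", "dead"),
                 rhs = c(x = "-k*x"), observed = "x", init = list(x = 1))
  sys <- assemble_system(m)
  gens <- solve_generators(sys)
  expect_length(gens, 1)
  expect_equal(gens[[1]]$exponents[["dead"]], 1L)
  expect_equal(gens[[1]]$exponents[["k"]], 0L)
})

test_that("symbolic and sampling constraint paths give identical nullspaces", {
  for (nm in catalogue_models()$name) {
    g1 <- solve_generators(assemble_system(get_model(nm),
                                           method = "symbolic"))
    g2 <- solve_generators(assemble_system(get_model(nm),
                                           method = "sampling"))
    expect_equal(length(g1), length(g2), info = nm)
    e1 <- lapply(g1, expo_sorted)
    e2 <- lapply(g2, expo_sorted)
    expect_setequal(lapply(e1, unname), lapply(e2, unname))
  }
})

test_that("permuting parameter declaration order permutes generator entries", {
  perm <- ode_model(states = c("x1", "x2"),
                    params = c("lambda4", "lambda2", "lambda1", "lambda3"),
                    rhs = c(x1 = "lambda1*x1^2 + lambda2*x1*x2",
                            x2 = "lambda3*x1^2 + lambda4*x1*x2"),
                    observed = "x1", init = list(x1 = 0, x2 = 0))
  g <- solve_generators(assemble_system(perm))
  gref <- solve_generators(assemble_system(parse_model(twostate_doc())))
  expect_equal(expo_sorted(g[[1]]), expo_sorted(gref[[1]]))
})

test_that("duplicate constraint rows do not change the nullspace", {
  sys <- assemble_system(parse_model(death_doc()))
  sys2 <- sys
  sys2$matrix <- scalesid:::rqm_rbind(
    sys$matrix, list(num = sys$matrix$num[1, , drop = FALSE],
                     den = sys$matrix$den[1, , drop = FALSE]))
  expect_equal(lapply(solve_generators(sys2), expo_sorted),
               lapply(solve_generators(sys), expo_sorted))
})

test_that("exact rational nullspace is exact on random integer matrices", {
  set.seed(42)
  for (i in 1:20) {
    nr <- sample(1:5, 1); nc <- sample(2:6, 1)
    M <- matrix(sample(-4:4, nr * nc, replace = TRUE), nr, nc)
    basis <- scalesid:::rqm_nullspace(scalesid:::rqm(M))
    expect_equal(length(basis), nc - qr(M)$rank)
    for (v in basis) {
      for (r in seq_len(nr)) {
        dot <- scalesid:::rq_dot(scalesid:::rq(M[r, ]), v)
        expect_true(scalesid:::rq_is_zero(dot))
      }
    }
  }
})
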