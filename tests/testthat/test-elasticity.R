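# Numerical cross-validation of the symbolic verdicts.

test_that("sensitivities match the closed-form death-model solution", {
  m <- get_model("death")
  pv <- c(lambda1 = 0.8, lambda2 = 1.25, x0 = 1.3)
  times <- seq(0, 2, length.out = 21)
  tr <- simulate_with_sensitivities(m, pv, times)
  x_exact <- pv["x0"] * exp(-pv["lambda1"] * pv["lambda2"] * times)
  expect_equal(unname(tr$x[, "x"]), unname(x_exact), tolerance = 1e-8)
  # dx/dlambda1 = -lambda2 * t * x
  S_exact <- -pv["lambda2"] * times * x_exact
  expect_equal(unname(tr$S[, "x", "lambda1"]), unname(S_exact),
               tolerance = 1e-7)
  # dx/dx0 = x / x0
  expect_equal(unname(tr$S[, "x", "x_0"]), unname(x_exact / pv["x0"]),
               tolerance = 1e-7)
})

test_that("the variational initial condition is exact at t = 0", {
  for (nm in c("death", "death_immigration")) {
    m <- get_model(nm)
    tr <- simulate_with_sensitivities(m, sid_test_point(m, 1),
                                      seq(0, 0.5, length.out = 5))
    expect_equal(unname(tr$S[1, , m$params]),
                 unname(matrix(0, 1, length(m$params))[1, ]))
    expect_equal(unname(tr$S[1, , paste0(m$states, "_0")]), 1)
  }
  mt <- twostate_numeric()
  tr <- simulate_with_sensitivities(mt, sid_test_point(mt, 1),
                                    seq(0, 0.05, length.out = 5))
  expect_equal(unname(tr$S[1, , mt$params]),
               matrix(0, 2, 4), ignore_attr = TRUE)
  expect_equal(unname(tr$S[1, , paste0(mt$states, "_0")]), diag(2),
               ignore_attr = TRUE)
})

test_that("elasticity columns behave as log-log sensitivities", {
  # single-parameter decay: K column is -lambda*t exactly
  m <- ode_model(states = "x", params = "lambda", rhs = c(x = "-lambda*x"),
                 observed = "x", init = list(x = 2))
  times <- seq(0, 1.5, length.out = 16)
  lam <- 0.9
  tr <- simulate_with_sensitivities(m, c(lambda = lam), times)
  K <- elasticity_matrix(tr)
  expect_equal(unname(K[, "lambda"]), -lam * times, tolerance = 1e-7)

  # death model: the two parameter columns coincide, |K| = lambda1*lambda2*t
  md <- get_model("death")
  pv <- c(lambda1 = 0.8, lambda2 = 1.25, x0 = 1)
  trd <- simulate_with_sensitivities(md, pv, times)
  Kd <- elasticity_matrix(trd)
  expect_equal(unname(Kd[, "lambda1"]), unname(Kd[, "lambda2"]),
               tolerance = 1e-9)
  expect_equal(abs(unname(Kd[, "lambda1"])),
               pv["lambda1"] * pv["lambda2"] * times,
               tolerance = 1e-7, ignore_attr = TRUE)

  # K = 1 means a small relative bump in theta gives the same relative
  # response in x (finite-difference interpretation check on the x0 column)
  expect_equal(unname(Kd[, "x_0"]), rep(1, length(times)), tolerance = 1e-7)
  h <- 1e-6
  pv2 <- pv; pv2["x0"] <- pv["x0"] * (1 + h)
  tr2 <- simulate_with_sensitivities(md, pv2, times)
  rel_resp <- unname((tr2$x[5, "x"] - trd$x[5, "x"]) / trd$x[5, "x"] / h)
  expect_equal(rel_resp, unname(Kd[5, "x_0"]), tolerance = 1e-4)
})

test_that("sensitivities agree with central finite differences", {
  for (build in list(function() get_model("death_immigration"),
                     twostate_numeric)) {
    m <- build()
    pv <- sid_test_point(m, 2)
    times <- seq(0, 0.2, length.out = 6)
    tr <- simulate_with_sensitivities(m, pv, times)
    for (p in m$params) {
      h <- 1e-6 * pv[p]
      up <- pv; up[p] <- pv[p] + h
      dn <- pv; dn[p] <- pv[p] - h
      xu <- simulate_model(m, up, times, rtol = 1e-12, atol = 1e-14)
      xd <- simulate_model(m, dn, times, rtol = 1e-12, atol = 1e-14)
      fd <- (xu[, m$states, drop = FALSE] -
               xd[, m$states, drop = FALSE]) / (2 * h)
      S <- tr$S[, , p, drop = FALSE]
      scale <- max(abs(S), 1e-8)
      expect_lt(max(abs(fd - as.vector(S))) / scale, 1e-4)
    }
  }
})

test_that("generators predict linear dependence of elasticity columns", {
  md <- get_model("death")
  rd <- check_identifiability(md)
  trd <- simulate_with_sensitivities(md, sid_test_point(md, 1),
                                     seq(0, 1, length.out = 21))
  res <- dependence_check(elasticity_matrix(trd), md, rd$generators)
  expect_length(res, 1)
  expect_lt(res, 1e-6)

  mi <- get_model("death_immigration")
  ri <- check_identifiability(mi)
  expect_length(dependence_check(
    elasticity_matrix(simulate_with_sensitivities(
      mi, sid_test_point(mi, 1), seq(0, 1, length.out = 21))),
    mi, ri$generators), 0)

  mt <- twostate_numeric()
  rt <- check_identifiability(mt)
  trt <- simulate_with_sensitivities(mt, sid_test_point(mt, 1),
                                     seq(0, 0.1, length.out = 21))
  rest <- dependence_check(elasticity_matrix(trt), mt, rt$generators)
  expect_length(rest, 1)
  expect_lt(rest, 1e-6)
})

test_that("rank of K plus generator dimension accounts for all parameters", {
  cases <- list(list(m = get_model("death"), t_end = 1),
                list(m = get_model("death_immigration"), t_end = 1),
                list(m = twostate_numeric(), t_end = 0.1))
  for (cs in cases) {
    m <- cs$m
    rep <- check_identifiability(m)
    tr <- simulate_with_sensitivities(m, sid_test_point(m, 1),
                                      seq(0, cs$t_end, length.out = 25))
    K <- elasticity_matrix(tr)
    Kp <- K[stats::complete.cases(K), m$params, drop = FALSE]
    Kp <- Kp[rowSums(abs(Kp)) > 0, , drop = FALSE]
    d <- svd(Kp)$d
    rankK <- sum(d > 1e-8 * d[1])
    # nullspace dimension restricted to parameter columns
    if (length(rep$generators)) {
      G <- do.call(rbind, lapply(rep$generators, function(g)
        g$exponents[m$params]))
      nulldim <- qr(G)$rank
    } else nulldim <- 0
    expect_equal(rankK + nulldim, length(m$params),
                 info = paste(m$states, collapse = ","))
  }
})

test_that("finite scaling leaves observed trajectories invariant only for true generators", {
  md <- get_model("death")
  rd <- check_identifiability(md)
  pt <- sid_test_point(md, 4)
  expect_equal(finite_invariance_check(md, rd$generators[[1]], eps = 0,
                                       parameter_values = pt), 0)
  expect_lt(finite_invariance_check(md, rd$generators[[1]], eps = 0.5,
                                    parameter_values = pt), 1e-8)

  mi <- get_model("death_immigration")
  fake <- generator_from(lambda1 = 1, lambda2 = -1, x0 = 0)
  pt_i <- sid_test_point(mi, 4)
  devs <- vapply(c(0.1, 0.2, 0.4), function(e)
    finite_invariance_check(mi, fake, eps = e, parameter_values = pt_i),
    numeric(1))
  expect_gt(devs[1], 1e-4)
  expect_true(all(diff(devs) > 0))

  mt <- twostate_numeric()
  rt <- check_identifiability(mt)
  expect_lt(finite_invariance_check(mt, rt$generators[[1]], eps = 0.1,
                                    parameter_values = sid_test_point(mt, 4),
                                    times = seq(0, 0.1, length.out = 21)),
            1e-8)
})

test_that("integration blow-up is reported as a failure", {
  m <- ode_model(states = "x", params = "lambda", rhs = c(x = "lambda*x^2"),
                 observed = "x", init = list(x = 1))
  expect_error(
    suppressWarnings(simulate_model(m, c(lambda = 1),
                                    times = seq(0, 50, length.out = 11))),
    class = "scalesid_integration_failure")
})

test_that("trajectory CSV export writes the grids", {
  tmp <- tempfile(fileext = ".csv")
  tr <- simulate_with_sensitivities(get_model("death"),
                                    sid_test_point(get_model("death"), 1),
                                    seq(0, 1, length.out = 5))
  export_trajectory_csv(tr, tmp)
  df <- utils::read.csv(tmp)
  expect_equal(nrow(df), 5)
  expect_true(all(c("t", "x", "S_x_lambda1", "K_x_lambda1") %in% names(df)))
})
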