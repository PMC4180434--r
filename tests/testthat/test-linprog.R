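test_that("simplex finds exact fractional optima", {
  # 14 y = 3 x with x fixed to 6: the ATP-synthase gearing toy
  A <- matrix(c(-3, 14, 1, 0), 2, 2, byrow = TRUE)
  r <- solve_lp(c(0, 1), A, c(0, 6), maximize = TRUE)
  expect_equal(r$status, "optimal")
  expect_true(r$objval == as_rq("9/7"))
})

test_that("infeasible and unbounded problems are classified", {
  A <- matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(solve_lp(c(1, 1), A, c(1, 2))$status, "infeasible")
  r <- solve_lp(c(1, 0), matrix(c(1, -1), 1, 2), 0, maximize = TRUE)
  expect_equal(r$status, "unbounded")
  expect_equal(solve_lp(c(1, 0), matrix(c(1, -1), 1, 2), 0, maximize = TRUE,
                        arithmetic = "double")$status, "unbounded")
})

test_that("free variables and two-sided bounds are handled", {
  # max x1 s.t. x1 + x2 = 0, -3 <= x1 <= 5, x2 free -> x1 = 5
  r <- solve_lp(c(1, 0), matrix(c(1, 1), 1, 2), 0,
                lb = c(-3, -Inf), ub = c(5, Inf), maximize = TRUE)
  expect_true(r$objval == rq(5))
  expect_true(r$x[2] == rq(-5))
  # equality bound lb == ub pins the variable
  r2 <- solve_lp(c(1, 0), matrix(c(1, -2), 1, 2), 0,
                 lb = c(0, 3), ub = c(Inf, 3), maximize = FALSE)
  expect_true(r2$x[1] == rq(6))
})

test_that("exact and double backends agree with pracma on random LPs", {
  skip_if_not_installed("pracma")
  set.seed(7)
  n_checked <- 0
  for (i in 1:40) {
    n <- sample(3:6, 1); m <- sample(1:3, 1)
    A <- matrix(sample(-3:3, m * n, TRUE), m, n)
    b <- as.vector(A %*% sample(0:3, n, TRUE))   # feasible by construction
    cc <- sample(-10:10, n, TRUE) / 10
    mine_d <- solve_lp(cc, A, b, lb = 0, ub = 5, arithmetic = "double")
    mine_x <- solve_lp(cc, A, b, lb = 0, ub = 5)
    expect_equal(mine_d$status, mine_x$status)
    if (mine_d$status == "optimal") {
      expect_equal(as.numeric(mine_x$objval), mine_d$objval, tolerance = 1e-9)
      # bounds passed as inequality rows (x >= 0 is pracma's default)
      ref <- suppressWarnings(tryCatch(
        pracma::linprog(cc, A = diag(n), b = rep(5, n), Aeq = A, beq = b,
                        maxiter = 500),
        error = function(e) NULL))
      if (!is.null(ref) && is.finite(ref$fval)) {
        expect_equal(mine_d$objval, ref$fval, tolerance = 1e-6)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 10)   # the cross-check actually exercised cases
})
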