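test_that("identity kernels give the closed-form shrinkage Y/(1+lambda)", {
  withr::with_seed(31, {
    Y <- matrix(rbinom(12, 1, 0.5), 3, 4)
  })
  fit <- kron_rls_fit(diag(3), diag(4), Y, lambda = 1)
  expect_equal(unname(predict_scores(fit)), Y / 2)
  sc <- direct_solve(diag(3), diag(4), Y, lambda = 1)
  expect_equal(unname(sc), Y / 2)
})

test_that("lambda = 0 with strictly PD kernels interpolates the labels", {
  withr::with_seed(37, {
    Sm <- random_psd_kernel(5) + 0.1 * diag(5)
    Sm <- Sm / sqrt(outer(diag(Sm), diag(Sm)))
    St <- random_psd_kernel(4) + 0.1 * diag(4)
    St <- St / sqrt(outer(diag(St), diag(St)))
    Y <- matrix(rbinom(20, 1, 0.5), 5, 4)
  })
  fit <- kron_rls_fit(Sm, St, Y, lambda = 0)
  expect_lt(max(abs(predict_scores(fit) - Y)), 1e-8)
})

test_that("scalar problem and huge-lambda shrinkage behave as expected", {
  expect_equal(unname(direct_solve(matrix(1), matrix(1),
                                   matrix(1), lambda = 1)),
               matrix(0.5))
  withr::with_seed(41, {
    Sm <- random_psd_kernel(4); St <- random_psd_kernel(5)
    Y <- matrix(rbinom(20, 1, 0.5), 4, 5)
  })
  fit <- kron_rls_fit(Sm, St, Y, lambda = 1e9)
  expect_lt(max(abs(predict_scores(fit))), 1e-6)
  expect_error(direct_solve(diag(50), diag(50),
                            matrix(0, 50, 50), 1), "guard")
})

test_that("eigen route equals the dense Kronecker solve", {
  withr::with_seed(43, {
    for (rep in 1:20) {
      k <- sample(2:10, 1); l <- sample(2:10, 1)
      Sm <- random_psd_kernel(k); St <- random_psd_kernel(l)
      Y <- matrix(rbinom(k * l, 1, 0.4), k, l)
      lam <- sample(c(0.1, 1, 35), 1)
      f <- kron_rls_fit(Sm, St, Y, lam)
      d <- direct_solve(Sm, St, Y, lam)
      expect_lt(max(abs(unname(predict_scores(f)) - unname(d))), 1e-8)
    }
  })
})

test_that("prediction norm shrinks monotonically in lambda", {
  withr::with_seed(47, {
    Sm <- random_psd_kernel(6); St <- random_psd_kernel(7)
    Y <- matrix(rbinom(42, 1, 0.4), 6, 7)
  })
  norms <- vapply(c(0.01, 0.1, 1, 10, 100, 1000), function(lam) {
    sqrt(sum(predict_scores(kron_rls_fit(Sm, St, Y, lam))^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("scores are equivariant under miRNA permutation", {
  withr::with_seed(53, {
    Sm <- random_psd_kernel(5); St <- random_psd_kernel(6)
    Y <- matrix(rbinom(30, 1, 0.4), 5, 6)
    perm <- sample(5)
  })
  f1 <- predict_scores(kron_rls_fit(Sm, St, Y, 35))
  f2 <- predict_scores(kron_rls_fit(Sm[perm, perm], St, Y[perm, ], 35))
  expect_equal(unname(f2), unname(f1)[perm, ])
})

test_that("the fitted coefficients locally minimize the RLS objective", {
  withr::with_seed(59, {
    Sm <- random_psd_kernel(3); St <- random_psd_kernel(4)
    Y <- matrix(rbinom(12, 1, 0.5), 3, 4)
    lam <- 2
    K <- Sm %x% St
    y <- as.vector(t(Y))
    alpha <- solve(K + lam * diag(12), y)
    J <- function(a) sum((y - K %*% a)^2) + lam * sum(a * (K %*% a))
    J_star <- J(alpha)
    for (rep in 1:100) {
      expect_lte(J_star, J(alpha + rnorm(12, sd = 0.05)) + 1e-10)
    }
  })
})

test_that("degenerate inputs are rejected and zero labels give zero scores", {
  expect_error(kron_rls_fit(diag(3), diag(4), matrix(0, 4, 3), 1),
               "dimension mismatch")
  expect_error(kron_rls_fit(diag(3), diag(3), matrix(0, 3, 3), -1),
               "lambda")
  Y0 <- matrix(0, 3, 4)
  expect_true(all(predict_scores(kron_rls_fit(diag(3), diag(4),
                                              Y0, 1)) == 0))
  expect_error(predict_scores(structure(list(), class = "rls_model")),
               "fitted")
  # rank-deficient kernel at lambda = 0 is a hard error
  S1 <- matrix(1, 3, 3)
  expect_error(kron_rls_fit(S1, diag(2), matrix(1, 3, 2), 0), "singular")
})

test_that("model archives round-trip through JSON", {
  withr::with_seed(61, {
    Sm <- random_psd_kernel(3); St <- random_psd_kernel(4)
    Y <- matrix(rbinom(12, 1, 0.5), 3, 4,
                dimnames = list(paste0("m", 1:3), paste0("t", 1:4)))
  })
  fit <- kron_rls_fit(Sm, St, Y, 35)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(predict_scores(back), predict_scores(fit))
  expect_equal(back$lambda, 35)
})
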