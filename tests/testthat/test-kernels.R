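test_that("Gaussian profile kernel evaluates the radial formula", {
  V <- rbind(c(1, 0), c(0, 1), c(1, 0))
  K <- gaussian_profile_kernel(V)
  expect_equal(K[1, 3], 1)              # identical profiles
  expect_equal(K[1, 2], exp(-2))        # phi = 1, ||diff||^2 = 2
  # doubling phi_prime squares the off-diagonal entries
  K2 <- gaussian_profile_kernel(V, phi_prime = 2)
  expect_equal(K2[1, 2], K[1, 2]^2)
  expect_error(gaussian_profile_kernel(matrix(0, 3, 2)), "zero norm")
})

test_that("Gaussian profile kernel matches a literal double-loop oracle", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(5:20, 1)
      V <- matrix(rbinom(n * 8, 1, 0.3), n, 8)
      if (all(V == 0)) next
      expect_lt(max(abs(gaussian_profile_kernel(V) - gp_kernel_oracle(V))),
                1e-12)
    }
  })
})

test_that("scalar Gaussian kernel uses the second-moment bandwidth", {
  K <- scalar_gaussian_kernel(c(1, 3))
  expect_equal(K[1, 2], exp(-0.8))      # gamma = 0.2, diff^2 = 4
  expect_equal(unname(scalar_gaussian_kernel(c(-2, -2, -2))),
               matrix(1, 3, 3))
  expect_warning(K0 <- scalar_gaussian_kernel(c(0, 0)), "unit bandwidth")
  expect_equal(unname(K0), matrix(1, 2, 2))
})

test_that("alignment kernel normalizes and clips Needleman-Wunsch scores", {
  seqs <- c(a = "AAAA", b = "UUUU", c = "AAAA")
  K <- nw_similarity_kernel(seqs)
  expect_equal(K["a", "c"], 1)          # identical sequences
  expect_equal(K["a", "b"], 0)          # score -4 normalized < 0, clipped
  K2 <- nw_similarity_kernel(c(x = "AUGC", y = "AUGC", z = "AUGG"))
  expect_gt(K2["x", "y"], K2["x", "z"]) # a mismatch lowers similarity
})

test_that("alignment kernel agrees with an explicit DP oracle", {
  withr::with_seed(17, {
    seqs <- replicate(8, rand_rna(sample(4:7, 1)))
    names(seqs) <- paste0("s", seq_along(seqs))
    K <- nw_similarity_kernel(seqs)
    raw <- outer(seq_along(seqs), seq_along(seqs),
                 Vectorize(function(i, j) nw_score_oracle(seqs[i], seqs[j])))
    self <- diag(raw)
    want <- pmax(raw / sqrt(outer(self, self)), 0)
    diag(want) <- 1
    expect_lt(max(abs(unname(K) - want)), 1e-12)
  })
})

test_that("kernel integration is the weighted entrywise mean", {
  ids <- c("a", "b")
  mk <- function(off) {
    matrix(c(1, off, off, 1), 2, 2, dimnames = list(ids, ids))
  }
  ks <- lapply(c(0.2, 0.4, 0.6, 0.8), mk)
  expect_identical(integrate_kernels(ks, c(1, 0, 0, 0)), ks[[1]])
  expect_equal(integrate_kernels(ks, c(1, 1, 1, 1))[1, 2], 0.5)
  expect_equal(integrate_kernels(ks, c(2, 1, 1, 0))[1, 2], 0.35)
  expect_error(integrate_kernels(ks, c(0, 0, 0, 0)), "positive")
  ks_bad <- ks
  dimnames(ks_bad[[2]]) <- list(c("a", "z"), c("a", "z"))
  expect_error(integrate_kernels(ks_bad, c(1, 1, 1, 1)), "entity list")
  # integrating identical kernels returns the kernel for any weights
  K <- random_psd_kernel(6)
  expect_equal(integrate_kernels(list(K, K, K, K), c(3, 1, 0.5, 2)), K)
})

test_that("nearest PSD projection clips, rescales, and fixes PSD input", {
  K <- random_psd_kernel(5)
  expect_identical(nearest_psd(K), K)
  expect_identical(nearest_psd(diag(3)), diag(3))
  B <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  out <- nearest_psd(B)
  expect_gte(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  expect_equal(diag(out), c(1, 1))
})

test_that("every kernel builder yields symmetric unit-diagonal [0,1] output", {
  withr::with_seed(19, {
    seqs <- replicate(10, rand_rna(15L))
    names(seqs) <- paste0("s", 1:10)
    kernels <- list(
      nw = nw_similarity_kernel(seqs),
      gp = gaussian_profile_kernel(matrix(rbinom(50, 1, 0.4), 10, 5)),
      sc = scalar_gaussian_kernel(rnorm(10) - 5)
    )
    for (K in kernels) {
      expect_lt(max(abs(K - t(K))), 1e-10)
      expect_equal(unname(diag(K)), rep(1, nrow(K)))
      expect_true(all(K >= 0 & K <= 1 + 1e-12))
    }
  })
})

test_that("kernels are equivariant under entity permutation", {
  withr::with_seed(23, {
    seqs <- stats::setNames(replicate(6, rand_rna(12L)), paste0("s", 1:6))
    perm <- sample(6)
    K <- nw_similarity_kernel(seqs)
    Kp <- nw_similarity_kernel(seqs[perm])
    expect_equal(Kp, K[perm, perm])
    V <- matrix(rbinom(24, 1, 0.5), 6, 4,
                dimnames = list(names(seqs), NULL))
    G <- gaussian_profile_kernel(V)
    Gp <- gaussian_profile_kernel(V[perm, , drop = FALSE])
    expect_equal(Gp, G[perm, perm])
  })
})
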