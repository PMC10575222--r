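test_that("model wiring gives the three heads their output sizes", {
  m <- build_model(4, 94, feature_dim = 16, seed = 0, input_shape = c(12, 16),
                   conv_channels = 4, branch_hidden = 8, head_hidden = 5)
  expect_equal(ncol(m$par[["h2.out.W"]]), 4)     # variety head
  expect_equal(ncol(m$par[["h3.out.W"]]), 2)     # domain head
  expect_equal(ncol(m$par[["h1.out.W"]]), 8)     # 4 varieties x 2 domains
  x <- array(rnorm(12 * 16 * 94), c(12, 16, 94))
  f <- separate(m, x)
  expect_equal(dim(classify_class(m, f)), c(1, 4))
  expect_equal(dim(classify_domain(m, f)), c(1, 2))
  expect_equal(dim(classify_domain_class(m, f)), c(1, 8))
})

test_that("initialization is deterministic in the seed", {
  a <- build_model(3, 10, seed = 4, input_shape = c(10, 10), conv_channels = 3)
  b <- build_model(3, 10, seed = 4, input_shape = c(10, 10), conv_channels = 3)
  c <- build_model(3, 10, seed = 5, input_shape = c(10, 10), conv_channels = 3)
  expect_identical(a$par, b$par)
  expect_false(identical(a$par, c$par))
  # parameter count is a pure function of the dimensions
  expect_identical(a$config$n_params, c$config$n_params)
})

test_that("degenerate and identical inputs behave predictably", {
  m <- tiny_model(tiny_data(n_per_class = 1))
  zero <- array(0, c(8, 10, 20))
  f <- separate(m, zero)
  expect_true(all(is.finite(c(f$F_n, f$F_c, f$F_d))))
  x <- array(rnorm(8 * 10 * 20), c(8, 10, 20))
  expect_identical(separate(m, x), separate(m, x))
})

test_that("inference-mode features are independent of batching", {
  data <- tiny_data(n_per_class = 2)
  m <- tiny_model(data)
  xb <- array(rnorm(8 * 10 * 20 * 5), c(8, 10, 20, 5))
  fb <- separate(m, xb)
  for (i in 1:5) {
    fi <- separate(m, xb[, , , i])
    expect_equal(unclass(fb)$F_n[i, ], drop(fi$F_n), tolerance = 1e-12)
    expect_equal(unclass(fb)$F_c[i, ], drop(fi$F_c), tolerance = 1e-12)
  }
})

test_that("head outputs are normalized probabilities, uniform at zero logits", {
  data <- tiny_data(n_per_class = 1)
  m <- tiny_model(data)
  f <- separate(m, array(rnorm(8 * 10 * 20 * 3), c(8, 10, 20, 3)))
  for (p in list(classify_class(m, f), classify_domain(m, f),
                 classify_domain_class(m, f))) {
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  }
  # force zero logits at the output layer
  m0 <- m
  m0$par[["h2.out.W"]][] <- 0; m0$par[["h2.out.b"]][] <- 0
  m0$par[["h1.out.W"]][] <- 0; m0$par[["h1.out.b"]][] <- 0
  expect_equal(classify_class(m0, f)[1, ], rep(0.25, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(classify_domain_class(m0, f)[1, ], rep(1 / 8, 8),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("non-canonical input shapes raise a geometry error", {
  m <- tiny_model(tiny_data(n_per_class = 1))
  expect_error(separate(m, array(0, c(9, 10, 20))),
               class = "adfs_geometry_error")
  expect_error(build_model(1, 10), class = "adfs_construction_error")
  expect_error(build_model(4, 10, feature_dim = 0),
               class = "adfs_construction_error")
})

test_that("gradient reversal is the identity forward, -lambda backward", {
  x <- c(0.3, -1.2, 2.5, 0, 4.1)
  expect_identical(gradient_reverse(x, 1), x)
  # finite-difference oracle on f(x) = sum(gradient_reverse(x, lambda))
  eps <- 1e-6
  for (lam in c(0, 0.5, 1, 2)) {
    fd <- vapply(seq_along(x), function(i) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      (sum(gradient_reverse(xp, lam)) - sum(gradient_reverse(xm, lam))) / (2 * eps)
    }, 1)
    back <- gradient_reverse_backward(rep(1, 5), lam)
    expect_equal(back, -lam * fd, tolerance = 1e-4)
  }
  expect_identical(gradient_reverse_backward(c(3, -2), 0), c(0, 0))
})
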