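test_that("spec_from_cube estimates marginals and expanded correlation targets", {
  cube <- make_reference_cube(n = 2000, seed = 1)
  spec <- spec_from_cube(cube)
  expect_length(spec$features, 35)
  expect_equal(dim(spec$correlations), c(35, 35)) # all continuous/binary
  expect_equal(unname(diag(spec$correlations)), rep(1, 35))

  # two identical columns give target off-diagonal 1
  twin <- tibble::tibble(a = rnorm(100))
  twin$b <- twin$a
  sp <- spec_from_cube(twin)
  expect_equal(sp$correlations["a", "b"], 1.0)

  # constant column kept as marginal, dropped from correlation targets
  const <- tibble::tibble(a = rnorm(50), c = rep(2, 50))
  expect_warning(spc <- spec_from_cube(const), "constant")
  expect_length(spc$features, 2)
  expect_equal(colnames(spc$correlations), "a")

  expect_error(spec_from_cube(tibble::tibble(a = 1)), ">= 2 rows")
})

test_that("categorical cube columns expand to one indicator per level", {
  cube <- tibble::tibble(
    num = rnorm(300),
    grp = sample(c("a", "b", "c"), 300, replace = TRUE)
  )
  spec <- spec_from_cube(cube)
  expect_setequal(colnames(spec$correlations),
                  c("num", "grp.a", "grp.b", "grp.c"))
})

test_that("independent targets stay independent", {
  spec <- feature_spec(list(
    list(name = "u", type = "continuous", dist = list(family = "normal")),
    list(name = "v", type = "continuous", dist = list(family = "normal"))
  ))
  x <- simulate_features(spec, 10000, seed = 4)
  expect_lt(abs(cor(x$u, x$v)), 0.05)
})

test_that("skewed marginals reach the target correlation at large n", {
  target_r <- 0.6
  spec <- feature_spec(
    list(
      list(name = "skew", type = "continuous",
           dist = list(family = "gamma", shape = 1, rate = 1)), # exponential
      list(name = "norm", type = "continuous", dist = list(family = "normal"))
    ),
    correlations = list(list("skew", "norm", target_r))
  )
  x <- simulate_features(spec, 10000, seed = 8)
  r <- cor(x$skew, x$norm)
  expect_lt(abs(r - target_r), 0.05)

  # independent oracle: Gaussian copula at the loop's matched latent
  # correlation produces the same realized Pearson correlation
  set.seed(99)
  rho <- 0.65 # latent correlation above the Pearson target, as the loop finds
  z1 <- rnorm(10000)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(10000)
  o1 <- qexp(pnorm(z1))
  o2 <- qnorm(pnorm(z2))
  expect_lt(abs(cor(o1, o2) - r), 0.05)
})

test_that("binary marginals are preserved", {
  spec <- feature_spec(list(list(name = "z", type = "binary", p = 0.3)))
  x <- simulate_features(spec, 10000, seed = 2)
  expect_lt(abs(mean(x$z) - 0.3), 0.02)
})

test_that("categorical synthesis respects level probabilities and correlations survive", {
  spec <- feature_spec(
    features = list(
      list(name = "age", type = "continuous",
           dist = list(family = "normal", mean = 60, sd = 10)),
      list(name = "grp", type = "categorical", levels = c("a", "b", "c"),
           probs = c(0.5, 0.3, 0.2))
    ),
    correlations = list(list("age", "grp.a", -0.3))
  )
  x <- simulate_features(spec, 10000, seed = 5)
  pr <- prop.table(table(x$grp))
  expect_lt(max(abs(pr[c("a", "b", "c")] - c(0.5, 0.3, 0.2))), 0.05)
  r <- cor(x$age, as.numeric(x$grp == "a"))
  expect_lt(abs(r - (-0.3)), 0.15) # decoding to levels blurs indicator correlations
})

test_that("cube-driven synthesis reproduces marginal distributions", {
  cube <- make_reference_cube(n = 4000, seed = 10)
  spec <- spec_from_cube(cube)
  x <- simulate_features(spec, 4000, seed = 11)
  expect_lt(attr(x, "rmsr"), 0.05)
  cmp <- compare_features(x, cube)
  ok <- cmp[!cmp$skipped, ]
  expect_gte(mean(!ok$flagged), 0.95)
})

test_that("realized feature means stabilize as n grows", {
  spec <- feature_spec(list(
    list(name = "lab", type = "continuous",
         dist = list(family = "lognormal", meanlog = 1, sdlog = 0.6))
  ))
  spread <- vapply(c(200, 3000), function(n) {
    means <- vapply(1:8, function(i) {
      mean(simulate_features(spec, n, seed = 100 * n + i)$lab)
    }, 0)
    sd(means)
  }, 0)
  expect_lt(spread[2], spread[1])
})

test_that("positive-definiteness repair and failure paths behave", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- -0.9 # badly inconsistent
  expect_error(
    feature_spec(
      list(
        list(name = "a", type = "binary", p = 0.5),
        list(name = "b", type = "binary", p = 0.5),
        list(name = "c", type = "binary", p = 0.5)
      ),
      correlations = list(list("a", "b", 0.9), list("a", "c", 0.9),
                          list("b", "c", -0.9))
    ),
    "eigenvalue"
  )
  r <- repair_pd(m)
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(unname(diag(r)), rep(1, 3))
})
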