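test_that("Bray-Curtis distances match a double-loop recomputation and the
           all-zero conventions", {
  set.seed(5)
  m <- matrix(runif(20), 5, 4, dimnames = list(paste0("S", 1:5), NULL))
  d <- abundance_distance(m, "bray_curtis")
  expect_equal(as.matrix(d), bray_oracle(m), ignore_attr = TRUE,
               tolerance = 1e-12)
  # identical rows -> 0; disjoint support -> 1
  m2 <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  d2 <- as.matrix(abundance_distance(m2, "bray_curtis"))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  # zero rows: 1 against signal, 0 against another zero row
  m3 <- rbind(a = c(0, 0), b = c(0, 0), c = c(2, 1))
  d3 <- as.matrix(abundance_distance(m3, "bray_curtis"))
  expect_equal(d3["a", "b"], 0)
  expect_equal(d3["a", "c"], 1)
})

test_that("environmental distances are Euclidean on per-variable z-scores", {
  env <- data.frame(water_sample_id = c("w1", "w2", "w3"),
                    x = c(0, 3, 6), y = c(1000, 3000, 2000))
  # single variable without standardization: plain 1-D distances
  d <- env_distance(env, "x", standardize = FALSE)
  expect_equal(as.vector(d), c(3, 6, 3))
  # z-scoring equalizes wildly different scales
  dz <- as.matrix(env_distance(env, c("x", "y"), standardize = TRUE))
  zx <- scale(env$x); zy <- scale(env$y)
  expect_equal(dz["w1", "w2"],
               sqrt((zx[1] - zx[2])^2 + (zy[1] - zy[2])^2))
  expect_equal(sd(zx), 1)
  # zero-variance variables are dropped with a warning
  env2 <- data.frame(a = rep(1.5, 4), b = c(1, 2, 4, 8))
  expect_warning(d0 <- env_distance(env2, standardize = TRUE),
                 "zero-variance")
  expect_equal(as.vector(d0),
               as.vector(dist(scale(env2$b))))
  expect_error(suppressWarnings(env_distance(env2[, "a", drop = FALSE])),
               "positive variance")
})

test_that("Mantel r is the triangle Pearson correlation and matches vegan", {
  dx <- rand_dist(10, 101)
  dy <- rand_dist(10, 202)
  m <- mantel_test(dx, dy, n_permutations = 499, seed = 7)
  expect_equal(m$r, cor(as.vector(dx), as.vector(dy)))
  v <- vegan::mantel(dx, dy, permutations = 99)
  expect_equal(m$r, unname(v$statistic))
  expect_gte(m$p_value, 1 / (499 + 1))
  # identity: r = 1, smallest achievable p
  mi <- mantel_test(dx, dx, n_permutations = 199, seed = 1)
  expect_equal(mi$r, 1)
})

test_that("Mantel r is invariant under a common relabeling of both
           matrices", {
  dx <- rand_dist(8, 11)
  dy <- rand_dist(8, 22)
  r0 <- mantel_test(dx, dy, n_permutations = 9, seed = 1)$r
  set.seed(33)
  p <- sample(8)
  perm_dist <- function(d) {
    m <- as.matrix(d)[p, p]
    dimnames(m) <- list(paste0("S", 1:8), paste0("S", 1:8))
    as.dist(m)
  }
  r1 <- mantel_test(perm_dist(dx), perm_dist(dy), n_permutations = 9,
                    seed = 1)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("exhaustive Mantel p equals brute-force enumeration over all 120
           relabelings", {
  for (s in c(1, 2, 3)) {
    dx <- rand_dist(5, 400 + s)
    set.seed(500 + s)
    dy_m <- as.matrix(dx) + as.matrix(dist(matrix(rnorm(15), 5)))
    dimnames(dy_m) <- list(paste0("S", 1:5), paste0("S", 1:5))
    dy <- as.dist(dy_m)
    m <- mantel_test(dx, dy, exhaustive = TRUE)
    expect_equal(m$n_permutations, 120)
    expect_equal(m$p_value, mantel_exhaustive_oracle(dx, dy))
  }
})

test_that("partial Mantel matches vegan, controls for dz, and its exhaustive
           mode matches brute force", {
  dx <- rand_dist(9, 61); dy <- rand_dist(9, 62); dz <- rand_dist(9, 63)
  pm <- partial_mantel_test(dx, dy, dz, n_permutations = 99, seed = 5)
  v <- vegan::mantel.partial(dx, dy, dz, permutations = 49)
  expect_equal(pm$r, unname(v$statistic))
  # a shared driver partialled out: r collapses relative to the plain test
  set.seed(4)
  z_pts <- matrix(rnorm(20), 10)
  dxs <- dist(z_pts + matrix(rnorm(20, 0, 0.3), 10))
  dys <- dist(z_pts + matrix(rnorm(20, 0, 0.3), 10))
  dzs <- dist(z_pts)
  plain_r <- mantel_test(dxs, dys, n_permutations = 9)$r
  part_r <- partial_mantel_test(dxs, dys, dzs, n_permutations = 9)$r
  expect_gt(plain_r, 0.5)
  expect_lt(part_r, plain_r - 0.2)
  expect_error(partial_mantel_test(dx, dy, dy, 99), "collinear")
  # with independent dz the partial r stays close to the plain r
  set.seed(9)
  dr <- replicate(60, {
    a <- rand_dist(10, sample.int(1e6, 1))
    b <- rand_dist(10, sample.int(1e6, 1))
    c_ <- rand_dist(10, sample.int(1e6, 1))
    abs(partial_mantel_test(a, b, c_, n_permutations = 9)$r -
          mantel_test(a, b, n_permutations = 9)$r)
  })
  expect_lt(mean(dr), 0.05)

  # exhaustive partial mode against enumeration built from first principles
  dx5 <- rand_dist(5, 81); dy5 <- rand_dist(5, 82); dz5 <- rand_dist(5, 83)
  pe <- partial_mantel_test(dx5, dy5, dz5, exhaustive = TRUE)
  xv <- as.vector(dx5); zv <- as.vector(dz5)
  M <- as.matrix(dy5); lt <- lower.tri(M)
  rx <- resid(lm(xv ~ zv))
  pr <- function(y) cor(rx, resid(lm(y ~ zv)))
  rs <- vapply(perms_oracle(5), function(p) pr(M[p, p][lt]), numeric(1))
  expect_equal(pe$p_value, mean(rs >= pr(M[lt]) - 1e-12))
})

test_that("errors on degenerate distance inputs", {
  dx <- rand_dist(6, 1)
  flat <- as.dist(matrix(1, 6, 6) - diag(6))
  expect_error(mantel_test(dx, flat), "zero variance")
  small <- rand_dist(3, 2)
  expect_error(mantel_test(small, small), "at least 4")
  expect_error(mantel_test(rand_dist(6, 1), rand_dist(7, 2)),
               "differ in size")
})

test_that("expression-abundance correlation returns the OLS fit and R^2", {
  x <- c(1, 2, 3, 4, 5)
  out <- expression_abundance_correlation(x, 2 * x + 1)
  expect_equal(out$pearson_r, 1)
  expect_equal(out$r_squared, 1)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 1)
  expect_error(expression_abundance_correlation(x, rep(1, 5)), "constant")
  expect_error(expression_abundance_correlation(x[1:2], x[1:2]),
               "at least 3")
  # null: mean R^2 ~ 1/(n-1)
  set.seed(8)
  r2 <- replicate(400, {
    expression_abundance_correlation(rnorm(20), rnorm(20))$r_squared
  })
  expect_lt(abs(mean(r2) - 1 / 19), 0.02)
  # planted correlation recovered: r = 0.9 -> R^2 ~ 0.81
  set.seed(10)
  r2p <- replicate(200, {
    a <- rnorm(50)
    b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(50)
    expression_abundance_correlation(a, b)$r_squared
  })
  expect_equal(mean(r2p), 0.81, tolerance = 0.03)
})
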