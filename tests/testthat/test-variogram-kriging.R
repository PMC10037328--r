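test_that("empirical variogram bins equal brute-force pair enumeration", {
  set.seed(31)
  n <- 15
  xy <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  z <- rnorm(n)
  emp <- empiricalVariogram(xy, z, nBins = 10)
  ## brute force: all pairs, same equal-width bins on [0, maxdist/2]
  pairs <- combn(n, 2)
  d <- sqrt(rowSums((xy[pairs[1, ], ] - xy[pairs[2, ], ])^2))
  dz2 <- (z[pairs[1, ]] - z[pairs[2, ]])^2
  maxLag <- max(d) / 2
  edges <- seq(0, maxLag, length.out = 11)
  for (r in seq_len(nrow(emp))) {
    b <- which.min(abs((edges[-1] + edges[-11]) / 2 - emp$center[r]))
    sel <- d > edges[b] & d <= edges[b + 1] |
      (b == 1 & d >= 0 & d <= edges[2])
    expect_equal(emp$npairs[r], sum(sel))
    expect_equal(emp$gamma[r], mean(dz2[sel]) / 2, tolerance = 1e-12)
  }
})

test_that("degenerate variogram inputs behave as the estimator dictates", {
  set.seed(32)
  xy <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  ## identical values -> all-zero semivariance
  emp <- empiricalVariogram(xy, rep(0.37, 20) + 0)
  expect_true(all(emp$gamma == 0))
  ## i.i.d. values of variance v -> flat at v (pure nugget)
  acc <- 0
  for (s in 1:40) {
    set.seed(s)
    acc <- acc + empiricalVariogram(xy, rnorm(20, 0, 2))$gamma
  }
  expect_equal(mean(acc / 40), 4, tolerance = 0.35)
  expect_error(empiricalVariogram(xy[1:5, ], rnorm(5)), "at least 10")
})

test_that("the exponential model is recovered exactly from exact bins", {
  h <- seq(5, 150, length.out = 15)
  g <- 0.1 + 1.0 * (1 - exp(-h / 30))
  emp <- data.frame(center = h, gamma = g, npairs = rep(40, 15))
  vm <- fitExponentialVariogram(emp)
  expect_equal(vm@nugget, 0.1, tolerance = 1e-6)
  expect_equal(vm@sill, 1.0, tolerance = 1e-6)
  expect_equal(vm@length, 30, tolerance = 1e-6)
  expect_false(vm@flat)
})

test_that("simulation-estimation-fit closes the loop on the length scale", {
  fl <- quickField(nSites = 150, extent = c(500, 200), ell = 30, sill = 1,
                   nugget = 0.1, seed = 7)
  est <- vapply(1:20, function(s) {
    z <- simulateGRF(fl$xy, fl$spec, seed = s)
    vm <- suppressWarnings(
      fitExponentialVariogram(empiricalVariogram(fl$xy, z, nBins = 20)))
    vm@length
  }, numeric(1))
  expect_lt(abs(median(est) - 30) / 30, 0.25)
})

test_that("a flat variogram raises the no-spatial-structure flag", {
  h <- seq(5, 150, length.out = 15)
  emp <- data.frame(center = h, gamma = rep(1.3, 15), npairs = rep(40, 15))
  expect_warning(vm <- fitExponentialVariogram(emp), "flat variogram")
  expect_true(vm@flat)
  expect_error(suppressWarnings(
    ordinaryKrige(cbind(runif(10), runif(10)), rnorm(10), vm)), "flat")
  expect_error(fitExponentialVariogram(emp[1:3, ]), "at least 4")
})

test_that("kriging is exact at the data with zero nugget and weights sum to 1", {
  fl <- quickField(nSites = 20, extent = c(100, 100), ell = 30, sill = 1,
                   nugget = 0, seed = 2)
  z <- simulateGRF(fl$xy, fl$spec, seed = 5)
  vm <- new("VariogramModel", binCenters = numeric(0), gammaHat = numeric(0),
            counts = numeric(0), nugget = 0, sill = 1, length = 30,
            flat = FALSE, converged = TRUE)
  kr <- ordinaryKrige(fl$xy, z, vm, grid = fl$xy)
  expect_lt(max(abs(kr$prediction - z)), 1e-8)
  expect_lt(max(abs(kr$variance)), 1e-8)
  grid <- makeGrid(fl$xy, nx = 15, ny = 15)
  kr2 <- ordinaryKrige(fl$xy, z, vm, grid = grid)
  expect_lt(max(abs(rowSums(attr(kr2, "lambda")) - 1)), 1e-10)
})

test_that("kriging equals an independent dense solve of the same system", {
  fl <- quickField(nSites = 20, extent = c(150, 150), ell = 40, sill = 2,
                   nugget = 0.3, seed = 3)
  z <- simulateGRF(fl$xy, fl$spec, seed = 9)
  vm <- new("VariogramModel", binCenters = numeric(0), gammaHat = numeric(0),
            counts = numeric(0), nugget = 0.3, sill = 2, length = 40,
            flat = FALSE, converged = TRUE)
  grid <- makeGrid(fl$xy, nx = 5, ny = 5)
  kr <- ordinaryKrige(fl$xy, z, vm, grid = grid)
  gam <- function(h) ifelse(h > 0, 0.3 + 2 * (1 - exp(-h / 40)), 0)
  n <- nrow(fl$xy)
  A <- rbind(cbind(gam(as.matrix(dist(fl$xy))), 1), c(rep(1, n), 0))
  for (gpt in c(1, 7, 25)) {
    d0 <- sqrt(colSums((t(fl$xy) - grid[gpt, ])^2))
    lam <- solve(A, c(gam(d0), 1))
    expect_equal(kr$prediction[gpt], sum(lam[1:n] * z), tolerance = 1e-10)
    expect_equal(kr$variance[gpt],
                 sum(lam[1:n] * gam(d0)) + unname(lam[n + 1]),
                 tolerance = 1e-10)
  }
  ## constant field: constant prediction, variance bounded by the nugget
  kc <- ordinaryKrige(fl$xy, rep(5, n), vm, grid = grid)
  expect_equal(kc$prediction, rep(5, 25), tolerance = 1e-10)
  ## duplicate data points are refused
  expect_error(ordinaryKrige(rbind(fl$xy, fl$xy[1, ]), c(z, z[1]), vm),
               "duplicate|singular")
})

test_that("thin-plate RBF interpolates exactly and reproduces affine data", {
  set.seed(41)
  xy <- cbind(runif(15, 0, 100), runif(15, 0, 100))
  z <- rnorm(15)
  rb <- rbfInterpolate(xy, z, grid = xy)
  expect_lt(max(abs(rb$prediction - z)), 1e-8)
  grid <- makeGrid(xy, nx = 9, ny = 9)
  aff <- 2 + 0.3 * xy[, 1] - 0.05 * xy[, 2]
  ra <- rbfInterpolate(xy, aff, grid = grid)
  expect_equal(ra$prediction, 2 + 0.3 * grid[, 1] - 0.05 * grid[, 2],
               tolerance = 1e-8)
  ## independent dense solve of the augmented thin-plate system
  tps <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  K <- tps(as.matrix(dist(xy)))
  P <- cbind(1, xy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(z, 0, 0, 0))
  gpt <- grid[33, ]
  d0 <- sqrt(colSums((t(xy) - gpt)^2))
  ref <- sum(sol[1:15] * tps(d0)) + sol[16] + sol[17] * gpt[1] +
    sol[18] * gpt[2]
  rg <- rbfInterpolate(xy, z, grid = grid)
  expect_equal(rg$prediction[33], ref, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(rbfInterpolate(xy[1:2, ], z[1:2]), "at least 3")
})

test_that("distribution diagnostics conserve counts and track normal samples", {
  set.seed(51)
  x <- rnorm(1000)
  d <- distributionDiagnostics(x)
  expect_equal(sum(d$histogram$count), 1000)
  ## Q-Q pairs of a standard-normal sample hug the identity line
  dev <- max(abs(d$qq$sample - d$qq$theoretical))
  expect_lt(dev, 0.5)    # comfortably inside the n = 1000 KS band
  kd <- d$kde
  expect_equal(sum(kd$density) * diff(kd$x[1:2]), 1, tolerance = 0.01)
  expect_error(distributionDiagnostics(c(1, 2)), "at least 3")
})
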