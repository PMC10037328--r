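test_that("zero-jitter positions fall on the exact regular grid", {
  spec <- fieldSpec(nSites = 4, extentM = c(100, 100), corrLengthM = 10,
                    gpsSigmaM = 0, seed = 1)
  pos <- samplePositions(spec)
  mpd <- c(111320, 111320 * cos(40.82 * pi / 180))
  xm <- (pos$lon - 16.08) * mpd[2]
  ym <- (pos$lat - 40.82) * mpd[1]
  expect_equal(sort(unique(round(xm, 6))), c(0, 100))
  expect_equal(sort(unique(round(ym, 6))), c(0, 100))
  expect_equal(nrow(unique(cbind(round(xm, 6), round(ym, 6)))), 4L)
})

test_that("position sampling is reproducible and non-degenerate", {
  spec <- fieldSpec(nSites = 60, extentM = c(500, 200), corrLengthM = 30,
                    seed = 99)
  p1 <- samplePositions(spec)
  p2 <- samplePositions(spec)
  expect_identical(p1, p2)
  xy <- projectToUTM(p1$lat, p1$lon)
  expect_gt(min(dist(xy)), 0)
  expect_equal(nrow(p1), 60L)
})

test_that("invalid field specs are rejected", {
  expect_error(fieldSpec(nSites = 2, extentM = c(10, 10)), "nSites")
  expect_error(fieldSpec(nSites = 5, extentM = c(-1, 10)), "positive")
  expect_error(fieldSpec(nSites = 5, corrLengthM = 0), "corrLengthM")
  expect_error(fieldSpec(nSites = 5, sill = 0, nugget = 0), "nugget \\+ sill")
})

test_that("GRF white-noise limit gives i.i.d. unit-variance values", {
  spec <- fieldSpec(nSites = 3, extentM = c(10, 10), corrLengthM = 1,
                    sill = 0, nugget = 1, seed = 1)
  pts <- rbind(c(0, 0), c(5, 5))
  draws <- vapply(seq_len(4000), function(s) simulateGRF(pts, spec, seed = s),
                  numeric(2))
  S <- tcrossprod(draws - rowMeans(draws)) / (ncol(draws) - 1)
  se <- sqrt(2 / ncol(draws))      # se of a variance / covariance estimate
  expect_lt(abs(S[1, 1] - 1), 3 * se)
  expect_lt(abs(S[2, 2] - 1), 3 * se)
  expect_lt(abs(S[1, 2]), 3 * se)
})

test_that("GRF perfectly-correlated limit gives near-equal site values", {
  ## at corr length 1e9 and h ~ 10 m the model itself leaves pairwise
  ## difference sd ~ sqrt(2h/l) ~ 1e-4, so equality is asserted at 1e-3
  spec <- fieldSpec(nSites = 3, extentM = c(10, 10), corrLengthM = 1e9,
                    sill = 1, nugget = 0, seed = 1)
  v <- simulateGRF(rbind(c(0, 0), c(5, 5), c(9, 1)), spec, seed = 3)
  expect_lt(diff(range(v)), 1e-3)
})

test_that("GRF empirical covariance matches the exponential model", {
  fl <- quickField(nSites = 200, extent = c(300, 300), ell = 30, sill = 1,
                   nugget = 0, seed = 5)
  xy <- fl$xy
  nDraw <- 50
  draws <- vapply(seq_len(nDraw), function(s) simulateGRF(xy, fl$spec, seed = s),
                  numeric(nrow(xy)))
  d <- as.matrix(dist(xy))
  ## center each draw, accumulate empirical covariance by distance bin
  Cemp <- tcrossprod(draws - rowMeans(draws)) / (nDraw - 1)
  bins <- cut(d[upper.tri(d)], breaks = c(15, 25, 35, 50, 70))
  ce <- tapply(Cemp[upper.tri(Cemp)], bins, mean)
  mids <- c(20, 30, 42.5, 60)
  cm <- exp(-mids / 30)
  expect_lt(max(abs(ce - cm)), 0.12)   # Monte-Carlo error at 50 draws
})

test_that("GRF reports a helpful error when the covariance is not PD", {
  spec <- fieldSpec(nSites = 3, extentM = c(10, 10), corrLengthM = 1e9,
                    sill = 1, nugget = 0, seed = 1)
  xy <- rbind(c(0, 0), c(1e-9, 0), c(0, 1e-9), c(1e-9, 1e-9))
  expect_error(simulateGRF(xy, spec), "positive definite")
})

test_that("bimodal field has two modes at the prescribed centers", {
  spec <- fieldSpec(nSites = 500, extentM = c(500, 200), corrLengthM = 100,
                    sill = 1, nugget = 0.09, seed = 11)
  pos <- samplePositions(spec)
  xy <- cbind(pos$x, pos$y)
  b <- simulateBimodalField(xy, spec, bimodalSpec(-0.5, 2.0, 0.3, 100))
  expect_equal(mean(b$membership), 0.3, tolerance = 0.01)
  dd <- distributionDiagnostics(b$values)
  expect_equal(geometab:::.kdeModes(dd$kde), 2L)
  modes <- dd$kde$x[which(diff(sign(diff(dd$kde$density))) == -2) + 1]
  expect_equal(sort(modes), c(-0.5, 2.0), tolerance = 0.15)
  ## the left peak holds more samples
  expect_gt(sum(!b$membership), sum(b$membership))
})

test_that("bimodal membership collapses to the low mode as fracHi -> 0", {
  fl <- quickField(nSites = 100, extent = c(200, 200), seed = 2)
  b <- simulateBimodalField(fl$xy, fl$spec, bimodalSpec(-0.5, 2, 0.005, 50))
  expect_lte(sum(b$membership), 1L)
  expect_lt(abs(mean(b$values[!b$membership]) + 0.5), 0.2)
})

test_that("bimodal membership is spatially clustered (join-count test)", {
  fl <- quickField(nSites = 150, extent = c(300, 300), seed = 4,
                   nugget = 0.09)
  b <- simulateBimodalField(fl$xy, fl$spec, bimodalSpec(-0.5, 2, 0.3, 150))
  W <- kernelWeights(fl$xy, k = 7, rowStandardize = FALSE)
  jc <- function(lab) sum(W@w * (lab[W@i] == lab[W@j]))
  obs <- jc(b$membership)
  set.seed(1)
  perm <- replicate(199, jc(sample(b$membership)))
  expect_gt(obs, mean(perm))
  expect_lte(mean(perm >= obs), 0.01)
})

test_that("sample variogram of the generator matches the model", {
  ## averaged over 30 seeds the empirical variogram tracks
  ## gamma(h) = nugget + sill (1 - exp(-h/l)) in [l/2, 2l]
  fl <- quickField(nSites = 150, extent = c(400, 250), ell = 30, sill = 1,
                   nugget = 0.1, seed = 8)
  acc <- NULL
  for (s in 1:30) {
    z <- simulateGRF(fl$xy, fl$spec, seed = 100 + s)
    emp <- empiricalVariogram(fl$xy, z, nBins = 20)
    acc <- if (is.null(acc)) emp$gamma else acc + emp$gamma
  }
  emp <- empiricalVariogram(fl$xy, simulateGRF(fl$xy, fl$spec, seed = 1))
  gbar <- acc / 30
  h <- emp$center
  sel <- h >= 15 & h <= 60 & emp$npairs >= 100  # skip thin first bins
  gmod <- 0.1 + 1 * (1 - exp(-h / 30))
  expect_lt(max(abs(gbar[sel] / gmod[sel] - 1)), 0.15)
})
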