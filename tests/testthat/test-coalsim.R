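test_that("simulation is deterministic given a seed and theta=0 yields S=0", {
  dem <- DemographicModel("pop", sizes = 1, thetaSite = 0,
                          modelType = "panmictic")
  spec <- LocusSimSpec("x", 300L)
  set.seed(3)
  s0 <- simulateLocus(dem, spec, 10L)
  expect_equal(length(s0@positions), 0L)
  expect_equal(ncol(s0@matrix), 0L)

  dem@thetaSite <- 5 / 300
  set.seed(9)
  a <- simulateLocus(dem, spec, 10L)
  set.seed(9)
  b <- simulateLocus(dem, spec, 10L)
  expect_identical(a@matrix, b@matrix)
  expect_identical(a@positions, b@positions)
})

test_that("panmictic runs track coalescent expectations (quick check)", {
  st <- simPanmicticStats(5, 10, 800, seed = 21)
  a1 <- sum(1 / (1:9))
  expect_lt(abs(mean(st$S) - 5 * a1), 4 * sd(st$S) / sqrt(nrow(st)))
  expect_lt(abs(mean(st$piLocus) - 5), 4 * sd(st$piLocus) / sqrt(nrow(st)))
  # E[TMRCA] = 1 - 1/n in 4*N0 units
  expect_lt(abs(mean(st$tmrca) - 0.9), 4 * sd(st$tmrca) / sqrt(nrow(st)))
})

test_that("rho = 0 site patterns always pass the four-gamete test", {
  dem <- DemographicModel("pop", sizes = 1, thetaSite = 5 / 300,
                          modelType = "panmictic")
  spec <- LocusSimSpec("x", 300L)
  set.seed(5)
  for (rep in 1:40) {
    sim <- simulateLocus(dem, spec, 15L)
    m <- sim@matrix
    S <- ncol(m)
    if (S < 2) next
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      gam <- unique(paste(m[, i], m[, j]))
      expect_lt(length(gam), 4)
    }
  }
})

test_that("recombination breaks perfect phylogeny but preserves E[S]", {
  dem <- DemographicModel("pop", sizes = 1, thetaSite = 10 / 300,
                          modelType = "panmictic")
  fourGameteFails <- function(m) {
    S <- ncol(m)
    if (S < 2) return(FALSE)
    for (i in seq_len(S - 1)) for (j in (i + 1):S)
      if (length(unique(paste(m[, i], m[, j]))) == 4) return(TRUE)
    FALSE
  }
  set.seed(13)
  specR <- LocusSimSpec("x", 300L, rhoLocus = 20)
  anyFail <- FALSE
  S <- numeric(400)
  for (i in 1:400) {
    sim <- simulateLocus(dem, specR, 12L)
    S[i] <- ncol(sim@matrix)
    if (!anyFail) anyFail <- fourGameteFails(sim@matrix)
  }
  expect_true(anyFail)  # recombination produces all four gametes sometimes
  a1 <- sum(1 / (1:11))
  # E[S] = theta * a1 independent of rho (recombination reduces variance)
  expect_lt(abs(mean(S) - 10 * a1), 4 * sd(S) / sqrt(400))
})

test_that("two-island builder validates and matches migration-drift theory", {
  expect_error(buildTwoIsland(list(Theta_OW = 0.01, Theta_NW = 0.01,
                                   M_OW = 0, M_NW = 0)),
               "never coalesce")
  m <- buildTwoIsland(list(Theta_OW = 0.01, Theta_NW = 0.005,
                           M_OW = 100, M_NW = 200))
  expect_equal(m@sizes, c(1, 0.5))
  expect_equal(m@migration[1, 2], 0.01 * 100)
  expect_equal(m@migration[2, 1], 0.01 * 200)
  expect_equal(nrow(m@events), 0L)

  # within-deme diversity is insensitive to M; Phi-ST decreases with M
  theta <- 3
  res <- lapply(c(0.5, 5, 50), function(M) {
    dem <- buildTwoIsland(list(Theta_OW = theta / 300, Theta_NW = theta / 300,
                               M_OW = M / (theta / 300),
                               M_NW = M / (theta / 300)))
    spec <- LocusSimSpec("x", 300L)
    phi <- numeric(500); wdiff <- numeric(500)
    for (i in 1:500) {
      set.seed(deriveSeed(37, i + M * 1000))
      sim <- simulateLocus(dem, spec, c(8L, 8L), returnMatrix = FALSE)
      counts <- sim@counts
      st <- simulatedLocusStats(sim)
      phi[i] <- st$phi_st
      x1 <- counts[, 1]
      wdiff[i] <- if (nrow(counts)) sum(x1 * (8 - x1)) / choose(8, 2) else 0
    }
    c(phi = mean(phi, na.rm = TRUE), w = mean(wdiff), se = sd(wdiff) / sqrt(500))
  })
  phis <- vapply(res, `[[`, numeric(1), "phi")
  expect_true(all(diff(phis) < 0))
  # E[within-deme pairwise diffs] = 2 * theta for two equal demes, any M
  for (r in res) expect_lt(abs(r[["w"]] - 2 * theta), 4 * r[["se"]])
})

test_that("isolation-migration builder limits behave correctly", {
  g <- 300
  base <- list(theta_OW = 3, theta_NW = 3, theta_A = 3, M_OW = 1, M_NW = 1,
               t = 0.02, s = 0.5)
  expect_error(buildIsolationMigration(modifyList(base, list(s = 1.2)), g),
               "founding fraction")
  m <- buildIsolationMigration(base, g)
  expect_equal(m@events$kind, c("split_join", "size_change"))
  expect_equal(m@thetaSite, 3 / 300)

  # t -> 0: within- and between-population diversity converge (panmixia)
  tiny <- modifyList(base, list(t = 1e-6))
  dem <- buildIsolationMigration(tiny, g)
  spec <- LocusSimSpec("x", 300L)
  w <- numeric(400); b <- numeric(400)
  for (i in 1:400) {
    set.seed(deriveSeed(61, i))
    sim <- simulateLocus(dem, spec, c(6L, 6L), returnMatrix = FALSE)
    cnt <- sim@counts
    if (!nrow(cnt)) next
    x1 <- cnt[, 1]; x2 <- cnt[, 2]
    w[i] <- (sum(x1 * (6 - x1)) + sum(x2 * (6 - x2))) / (2 * choose(6, 2))
    b[i] <- sum(x1 * (6 - x2) + x2 * (6 - x1)) / 36
  }
  expect_lt(abs(mean(w) - mean(b)) / mean(b), 0.15)

  # smaller NW founding fraction lowers NW diversity
  piNW <- function(s, seedBase) {
    dem <- buildIsolationMigration(modifyList(base, list(s = s, M_OW = 0.05,
                                                         M_NW = 0.05)), g)
    mean(vapply(1:400, function(i) {
      set.seed(deriveSeed(seedBase, i))
      sim <- simulateLocus(dem, spec, c(6L, 6L), returnMatrix = FALSE)
      cnt <- sim@counts
      if (!nrow(cnt)) return(0)
      x2 <- cnt[, 2]
      sum(x2 * (6 - x2)) / choose(6, 2)
    }, numeric(1)))
  }
  expect_lt(piNW(0.022, 71), piNW(0.5, 71))
})

test_that("bottleneck histories bound tB and encode the recovery size", {
  im <- list(theta_OW = 3, theta_NW = 3, theta_A = 2, M_OW = 1, M_NW = 1,
             t = 0.02, s = 0.3)
  set.seed(19)
  tBs <- replicate(200, {
    m <- buildBottleneck(im, thetaOwLamarc = 0.009, geomeanL = 300)
    ev <- m@events
    rec <- ev[ev$kind == "size_change" & ev$time > im$t / im$theta_OW, ]
    expect_equal(rec$value, 0.009 / (3 / 300))
    rec$time * im$theta_OW
  })
  expect_true(all(tBs >= im$t & tBs <= 2 * im$t))

  # deeper bottlenecks (smaller recovery-to-ancestor ratio... i.e. smaller
  # theta_A relative to recovery) reduce diversity monotonically
  spec <- LocusSimSpec("x", 300L)
  meanPi <- vapply(c(2, 0.5, 0.1), function(thA) {
    imA <- modifyList(im, list(theta_A = thA))
    mean(vapply(1:300, function(i) {
      set.seed(deriveSeed(83 + thA * 100, i))
      m <- buildBottleneck(imA, thetaOwLamarc = 0.009, geomeanL = 300,
                           tB = 2 * im$t)
      sim <- simulateLocus(m, spec, c(6L, 6L), returnMatrix = FALSE)
      simulatedLocusStats(sim)$pi
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanPi) < 0))
})

test_that("hybridization models keep donor-NW migration structurally zero", {
  im <- list(theta_OW = 3, theta_NW = 3, theta_A = 2, M_OW = 1, M_NW = 1,
             t = 0.02, s = 0.3)
  fd <- list(theta_fd_rel = 1.5, M_fd_to_OW = 1, M_OW_to_fd = 1,
             t_fd_rel = 0.5)
  m <- buildHybridization(im, fd, 300)
  expect_equal(length(m@demeNames), 3L)
  expect_equal(m@migration[2, 3], 0)
  expect_equal(m@migration[3, 2], 0)
  expect_error(buildHybridization(im, modifyList(fd, list(t_fd_rel = 1e-4)),
                                  300), "postdate")

  # a large, introgressing donor raises OW diversity
  spec <- LocusSimSpec("x", 300L)
  piOW <- function(fdDraw, seedBase) {
    m <- buildHybridization(im, fdDraw, 300)
    mean(vapply(1:300, function(i) {
      set.seed(deriveSeed(seedBase, i))
      sim <- simulateLocus(m, spec, c(8L, 4L, 0L), returnMatrix = FALSE)
      cnt <- sim@counts
      if (!nrow(cnt)) return(0)
      x1 <- cnt[, 1]
      sum(x1 * (8 - x1)) / choose(8, 2)
    }, numeric(1)))
  }
  noMig <- modifyList(fd, list(M_fd_to_OW = 0, M_OW_to_fd = 0))
  big <- modifyList(fd, list(theta_fd_rel = 10, M_fd_to_OW = 2))
  expect_gt(piOW(big, 91), piOW(noMig, 91))
})

test_that("realized sequences agree with the segregating-site matrix", {
  dem <- DemographicModel("pop", sizes = 1, thetaSite = 8 / 300,
                          modelType = "panmictic")
  spec <- LocusSimSpec("x", 300L)
  set.seed(2)
  sim <- simulateLocus(dem, spec, 12L)
  aln <- realizeSequences(sim)
  S <- ncol(sim@matrix)
  m <- as.matrix(aln@sequences)
  poly <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  expect_equal(poly, S)
  st <- locusStats(aln)
  expect_equal(st$pi, simulatedLocusStats(sim)$pi, tolerance = 1e-12)
  expect_equal(st$S, S)

  # S = 0 gives identical sequences
  dem0 <- DemographicModel("pop", sizes = 1, thetaSite = 0,
                           modelType = "panmictic")
  sim0 <- simulateLocus(dem0, spec, 5L)
  aln0 <- realizeSequences(sim0)
  expect_equal(length(unique(as.character(aln0@sequences))), 1L)

  smallL <- LocusSimSpec("x", 3L)
  set.seed(4)
  simBig <- simulateLocus(dem, LocusSimSpec("x", 300L), 20L)
  if (ncol(simBig@matrix) > 3)
    expect_error(realizeSequences(simBig, L = 3), "more segregating sites")
})

test_that("the C++ counts fast path equals the R reference statistics", {
  dem <- buildTwoIsland(list(Theta_OW = 0.01, Theta_NW = 0.008,
                             M_OW = 300, M_NW = 500))
  spec <- LocusSimSpec("x", 400L)
  set.seed(6)
  for (i in 1:25) {
    sim <- simulateLocus(dem, spec, c(10L, 10L), returnMatrix = FALSE)
    r <- simulatedLocusStats(sim)
    cpp <- coalfit:::counts_stats_cpp(sim@counts, c(10L, 10L), 400)
    expect_equal(r$pi, cpp[1], tolerance = 1e-12)
    expect_equal(r$phi_st, cpp[2], tolerance = 1e-12)
    expect_equal(r$tajd, cpp[3], tolerance = 1e-12)
    expect_equal(r$S, as.integer(cpp[4]))
  }
})

test_that("ms dialect writer and reader round trip", {
  dem <- DemographicModel("pop", sizes = 1, thetaSite = 5 / 300,
                          modelType = "panmictic")
  spec <- LocusSimSpec("x", 300L)
  set.seed(8)
  sims <- lapply(1:3, function(i) simulateLocus(dem, spec, 6L))
  f <- withr::local_tempfile(fileext = ".ms")
  writeMs(sims, f)
  back <- readMs(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$matrix, unname(sims[[i]]@matrix))
    expect_equal(back[[i]]$positions, as.numeric(sprintf("%.6f",
                 sims[[i]]@positions)))
  }
})
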