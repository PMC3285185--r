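smallPredictive <- function(nHist = 120, nLoci = 5, seed = 2,
                            nPerDeme = c(10, 10)) {
  sc <- syntheticScenario(nLoci = nLoci)
  p <- sc@params
  demog <- genHistoryPosterior(sc, "lamarc", nrows = 600)
  rates <- genRatePosterior(sc, nrows = 600)
  hist <- assembleHistories(demog, rates, NULL, p$loci, n = nHist,
                            seed = seed)
  posteriorPredictive(hist, nPerDeme = nPerDeme, seed = seed + 1)
}

test_that("tail p-values follow the plug-in two-tailed formula", {
  sims <- 1:1000 / 1000
  expect_equal(coalfit:::.tailP(0.5005, sims), 1)
  expect_equal(coalfit:::.tailP(2, sims), 0.002)    # above all simulations
  expect_equal(coalfit:::.tailP(-1, sims), 0.002)   # below all simulations
  expect_equal(coalfit:::.tailP(0.1, sims), 0.2)
})

test_that("predictive distributions are reproducible and self-consistent", {
  p1 <- smallPredictive()
  p2 <- smallPredictive()
  expect_identical(p1@pi, p2@pi)
  expect_identical(p1@tajd, p2@tajd)

  # dataset-level vectors recompute exactly from the stored matrices
  expect_equal(p1@datasetMeans$pi, rowMeans(p1@pi, na.rm = TRUE))
  cv <- apply(p1@phiSt, 1, sd, na.rm = TRUE) /
    abs(rowMeans(p1@phiSt, na.rm = TRUE))
  expect_equal(p1@datasetCVs$phi_st, cv)

  # coalescent noise alone keeps across-locus CV positive even for a
  # single repeated history
  sc <- syntheticScenario(nLoci = 6)
  demog <- genHistoryPosterior(sc, "lamarc", nrows = 50, dispersion = 0)
  rates <- genRatePosterior(sc, nrows = 50, noiseSd = 0)
  hist <- assembleHistories(demog, rates, NULL, sc@params$loci, n = 30,
                            replace = TRUE, seed = 3)
  pred <- posteriorPredictive(hist, nPerDeme = c(8, 8), seed = 5)
  expect_true(all(pred@datasetCVs$pi > 0, na.rm = TRUE))
})

test_that("relative-rate heterogeneity inflates the predictive CV of pi", {
  sc <- syntheticScenario(nLoci = 8, muRCV = 0.25)
  scFlat <- syntheticScenario(nLoci = 8, muRCV = 0)
  mk <- function(s, noise) {
    demog <- genHistoryPosterior(s, "lamarc", nrows = 400, dispersion = 0)
    rates <- genRatePosterior(s, nrows = 400, noiseSd = noise)
    hist <- assembleHistories(demog, rates, NULL, s@params$loci, n = 100,
                              seed = 11)
    posteriorPredictive(hist, nPerDeme = c(10, 10), seed = 12)
  }
  # same fragment lengths in the two panels, only muR differs
  expect_equal(sc@params$loci$length, scFlat@params$loci$length)
  cvHet <- mean(mk(sc, 0.1)@datasetCVs$pi, na.rm = TRUE)
  cvFlat <- mean(mk(scFlat, 0)@datasetCVs$pi, na.rm = TRUE)
  expect_gt(cvHet, cvFlat)
})

test_that("dataset-level GOF flags only genuine extremes", {
  pred <- smallPredictive()
  med <- data.frame(statistic = c("pi", "phi_st", "tajd"),
                    mean = vapply(pred@datasetMeans, median, numeric(1)),
                    cv = vapply(pred@datasetCVs, median, numeric(1)))
  g <- gofDataset(med, pred)
  expect_true(all(g@table$p > 0.5))
  expect_false(any(g@table$significant))

  extreme <- med
  extreme$mean[1] <- max(pred@datasetMeans$pi) * 10
  g2 <- gofDataset(extreme, pred)
  row <- g2@table[g2@table$statistic == "pi" & g2@table$measure == "mean", ]
  expect_equal(row$p, 2 / nrow(pred@pi))
  expect_true(row$significant)

  bad <- med; bad$mean[2] <- NA
  expect_error(gofDataset(bad, pred), "phi_st")
})

test_that("locus-level FDR decisions equal the step-up oracle", {
  pred <- smallPredictive()
  emp <- data.frame(locus = pred@lociIds,
                    pi = apply(pred@pi, 2, median))
  g <- gofLocusFdr(emp, pred, q = 0.05, statistics = "pi")
  expect_false(any(g@table$significant))
  expect_error(gofLocusFdr(data.frame(locus = "nope", pi = 1), pred),
               "missing from the predictive")

  # BH against the exhaustive oracle, including the worked p-vector
  pv <- c(0.001, 0.012, 0.02, 0.04, 0.2, rep(1, 17))
  expect_equal(p.adjust(pv, "BH") <= 0.05, oracleBH(pv, 0.05))
  set.seed(99)
  for (i in 1:60) {
    pv <- runif(22)^sample(1:4, 1)
    expect_equal(p.adjust(pv, "BH") <= 0.05, oracleBH(pv, 0.05))
  }
})

test_that("gof results are invariant to locus ordering", {
  pred <- smallPredictive()
  emp <- data.frame(locus = pred@lociIds,
                    pi = apply(pred@pi, 2, quantile, 0.2))
  g1 <- gofLocusFdr(emp, pred, statistics = "pi")
  perm <- sample(nrow(emp))
  g2 <- gofLocusFdr(emp[perm, ], pred, statistics = "pi")
  m1 <- g1@table[order(g1@table$locus), ]
  m2 <- g2@table[order(g2@table$locus), ]
  expect_equal(m1$p, m2$p)
  expect_equal(m1$significant, m2$significant)
})
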