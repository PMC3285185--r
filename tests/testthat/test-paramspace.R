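makeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("posterior tables validate their dialect and invariants", {
  dir <- withr::local_tempdir()
  lam <- data.frame(Theta_OW = c(0.01, 0.012), Theta_NW = c(0.004, 0.005),
                    M_OW = c(900, 1100), M_NW = c(1400, 1500),
                    r = c(0.2, 0.3))
  tab <- readPosterior(makeTsv(lam, file.path(dir, "lam.tsv")), "lamarc")
  expect_s4_class(tab, "PosteriorTable")
  expect_equal(tab@scaling, "per_site")
  expect_named(tab@table, c("Theta_OW", "Theta_NW", "M_OW", "M_NW", "r"))

  expect_error(readPosterior(makeTsv(lam[, -1], file.path(dir, "m.tsv")),
                             "lamarc"), "Theta_OW")

  rates <- data.frame(L1 = c(1.3, 1.0), L2 = c(1.3, 1.0))
  expect_error(readPosterior(makeTsv(rates, file.path(dir, "r.tsv")),
                             "rates"), "average 1")

  lam$M_OW[2] <- NA
  expect_error(readPosterior(makeTsv(lam, file.path(dir, "na.tsv")),
                             "lamarc"), "row 2.*M_OW")

  empty <- file.path(dir, "empty.tsv")
  file.create(empty)
  expect_error(readPosterior(empty, "im"), "empty")
})

test_that("rate rescaling follows the stated rules exactly", {
  d <- list(Theta_OW = 0.01, Theta_NW = 0.004, M_OW = 1000, M_NW = 1500)
  id <- rescaleLamarcDraw(d, muRDraw = 1)
  expect_equal(id[names(d)], d)

  r <- rescaleLamarcDraw(d, muRDraw = 2)
  expect_equal(r$Theta_OW, 0.005)
  expect_equal(r$M_OW, 2000)

  z <- rescaleLamarcDraw(d, muRDraw = 2, ploidy = 0.75)
  expect_equal(z$Theta_OW, 0.75 * 0.005)

  expect_error(rescaleLamarcDraw(d, muRDraw = -1), "positive")

  # round trip: rescaling by 1/muR is the exact inverse map
  inv <- rescaleLamarcDraw(r, muRDraw = 1 / 2)
  expect_equal(inv[names(d)], d, tolerance = 1e-12)
})

test_that("per-locus theta rescaling matches independent arithmetic", {
  L <- c(200, 300, 450)
  expect_equal(rescaleImDraw(2.4, rep(300, 3), rep(1, 3)), rep(2.4, 3))
  g <- exp(mean(log(L)))
  expect_equal(rescaleImDraw(2.4, L, rep(1, 3)), 2.4 / g * L)
  muR <- c(0.8, 1.0, 1.2)
  pl <- c(1, 0.75, 1)
  # spreadsheet-style recomputation, element by element
  manual <- vapply(1:3, function(i) 2.4 / g * L[i] * muR[i] * pl[i],
                   numeric(1))
  expect_equal(rescaleImDraw(2.4, L, muR, pl), manual, tolerance = 1e-12)
  expect_error(rescaleImDraw(2.4, L, muR[1:2]), "equal lengths")
})

test_that("history assembly is reproducible and preserves joint structure", {
  sc <- syntheticScenario(nLoci = 6)
  p <- sc@params
  demog <- genHistoryPosterior(sc, "lamarc", nrows = 5000, corr = 0.45)
  rates <- genRatePosterior(sc, nrows = 5000)
  recomb <- genHistoryPosterior(sc, "recomb", nrows = 5000)

  h1 <- assembleHistories(demog, rates, recomb, p$loci, n = 1000, seed = 4)
  h2 <- assembleHistories(demog, rates, recomb, p$loci, n = 1000, seed = 4)
  expect_identical(h1@draws, h2@draws)
  expect_identical(h1@muR, h2@muR)
  expect_identical(h1@rho, h2@rho)
  expect_equal(nHistories(h1), 1000L)

  # muR rows keep the mean-1 constraint
  expect_true(all(abs(rowMeans(h1@muR) - 1) < 1e-6))

  # marginals match the source posterior
  ks <- suppressWarnings(
    stats::ks.test(h1@draws$Theta_OW, demog@table$Theta_OW))
  expect_gt(ks$p.value, 0.01)

  # within-draw correlations survive assembly
  rhoSrc <- cor(demog@table$Theta_OW, demog@table$M_OW, method = "spearman")
  rhoHist <- cor(h1@draws$Theta_OW, h1@draws$M_OW, method = "spearman")
  expect_lt(abs(rhoSrc - rhoHist), 0.05)

  expect_error(assembleHistories(demog, rates, recomb, p$loci, n = 9000,
                                 seed = 1), "replace = TRUE")
  hr <- assembleHistories(demog, rates, recomb, p$loci, n = 6000,
                          replace = TRUE, seed = 1)
  expect_equal(nHistories(hr), 6000L)

  # subsetting keeps per-history structure aligned
  sub <- h1[11:20]
  expect_equal(nHistories(sub), 10L)
  expect_equal(sub@draws$Theta_OW, h1@draws$Theta_OW[11:20])
  expect_equal(sub@muR, h1@muR[11:20, ])
})

test_that("biweight joint estimates combine loci correctly", {
  set.seed(10)
  x <- rnorm(5000, 10, 2)
  single <- jointEstimate(list(x))
  dens <- density(x, bw = 0.9 * bw.nrd0(x), kernel = "biweight",
                  from = single$grid[1],
                  to = single$grid[length(single$grid)], n = 512)
  expect_equal(single$mode, dens$x[which.max(dens$y)], tolerance = 0.05)

  twice <- jointEstimate(list(x, x))
  expect_equal(twice$mode, single$mode, tolerance = 0.1)
  expect_lte(diff(twice$interval), diff(single$interval))

  # k identical Gaussian samples narrow the interval about 1/sqrt(k)
  k4 <- jointEstimate(list(x, x, x, x))
  ratio <- diff(k4$interval) / diff(single$interval)
  expect_lt(abs(ratio - 0.5), 0.075)

  y <- rnorm(5000, 1e6, 1)
  expect_error(jointEstimate(list(x, y)), "disjoint")
})
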