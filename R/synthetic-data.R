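#' Define a synthetic study scenario
#'
#' Ground truth for the synthetic-data generators.  Defaults emulate the
#' study conditions the package is designed for: a panel of 22 short
#' non-coding loci (fragment lengths uniform on 150-500 bp, one Z-linked
#' locus with ploidy factor 0.75), 50 sampled alleles per population,
#' among-locus relative substitution rates with a lognormal CV of 25%
#' normalised to mean 1, a per-site population mutation parameter of
#' roughly 0.009 for the larger (OW) population, and isolation-with-
#' migration truth values matching joint estimates typical of a Holarctic
#' split with a strong New World founder event (founding fraction ~2%).
#'
#' @param nLoci number of loci in the panel.
#' @param seed scenario seed; all generators derive their streams from it,
#'   so regeneration is bit-identical.
#' @param muRCV coefficient of variation of the relative substitution-rate
#'   truths.
#' @param lengthRange range of fragment lengths (bp).
#' @param zLinked index of the Z-linked locus (0 for none).
#' @param thetaSite per-site theta truth of the anchor population.
#' @param recombMean mean of the lognormal per-locus recombination-rate
#'   truths (per-site rate relative to the substitution rate).
#' @param dispersion lognormal sdlog of the pseudo-posterior spread around
#'   truth.
#' @param nPerDeme sampled alleles per population.
#' @param loci optional data.frame with columns `locus`, `length` and
#'   optionally `ploidy`, anchoring the scenario to an existing locus
#'   panel instead of a generated one.
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(nLoci = 22, seed = 20120222, muRCV = 0.25,
                              lengthRange = c(150L, 500L), zLinked = 1L,
                              thetaSite = 0.0092, recombMean = 0.25,
                              dispersion = 0.15, nPerDeme = c(50, 50),
                              loci = NULL) {
  set.seed(deriveSeed(seed, 1L))
  if (!is.null(loci)) {
    nLoci <- nrow(loci)
    ids <- as.character(loci$locus)
    lengths <- as.integer(loci$length)
    ploidy <- if ("ploidy" %in% names(loci)) loci$ploidy else {
      pl <- rep(1, nLoci)
      if (zLinked > 0) pl[zLinked] <- 0.75
      pl
    }
  } else {
    lengths <- sample(seq(lengthRange[1], lengthRange[2]), nLoci,
                      replace = TRUE)
    ids <- sprintf("L%02d", seq_len(nLoci))
    ploidy <- rep(1, nLoci)
    if (zLinked > 0) ploidy[zLinked] <- 0.75
  }
  # lognormal truths with the requested CV, renormalised to mean exactly 1
  sdlog <- sqrt(log(1 + muRCV^2))
  muR <- rlnorm(nLoci, -sdlog^2 / 2, sdlog)
  muR <- muR / mean(muR)
  recomb <- rlnorm(nLoci, log(recombMean) - 0.5^2 / 2, 0.5)
  params <- list(
    nLoci = nLoci, seed = seed,
    loci = data.frame(locus = ids, length = lengths, ploidy = ploidy,
                      muR = muR, recomb = recomb,
                      stringsAsFactors = FALSE),
    muRCV = muRCV, thetaSite = thetaSite, dispersion = dispersion,
    nPerDeme = nPerDeme,
    # demographic truths; the two-island and IM truths describe the same
    # per-site diversity level so the two dialects are mutually coherent
    twoIsland = list(Theta_OW = thetaSite, Theta_NW = 0.0042 / 0.0092 *
                       thetaSite, M_OW = 1010, M_NW = 1480),
    im = list(theta_OW = 2.53, theta_NW = 2.98, theta_A = 1.69,
              M_OW = 0.13, M_NW = 12.2, t = 0.032, s = 0.022),
    fd = list(theta_fd_rel = 1.5, M_fd_to_OW = 0.5, M_OW_to_fd = 0.5,
              t_fd_rel = 0.5))
  # rescale the IM per-locus truths so their per-site value matches
  # thetaSite on this panel
  g <- .geomean(lengths)
  sc <- thetaSite * g / params$im$theta_OW
  for (nm in c("theta_OW", "theta_NW", "theta_A", "t"))
    params$im[[nm]] <- params$im[[nm]] * sc
  new("SyntheticScenario", params = params)
}

setMethod("show", "SyntheticScenario", function(object) {
  p <- object@params
  cat("SyntheticScenario:", p$nLoci, "loci, seed", p$seed, "\n")
  cat("  theta_site =", p$thetaSite, ", muR CV =", p$muRCV,
      ", dispersion (sdlog) =", p$dispersion, "\n")
  cat("  fragment lengths", min(p$loci$length), "-", max(p$loci$length),
      "bp;", sum(p$loci$ploidy < 1), "Z-linked locus\n")
})

#' Pseudo-posterior of relative substitution rates
#'
#' Rows are pseudo-MCMC draws: independent lognormal noise around the
#' per-locus truths, renormalised so every row averages exactly 1 across
#' loci (the defining constraint of relative rates).
#'
#' @param scenario a [SyntheticScenario-class].
#' @param nrows number of draws.
#' @param noiseSd lognormal sdlog of the within-row noise (defaults to the
#'   scenario dispersion).
#' @return a `rates` [PosteriorTable-class].
#' @export
genRatePosterior <- function(scenario, nrows = 2000, noiseSd = NULL) {
  p <- scenario@params
  if (is.null(noiseSd)) noiseSd <- p$dispersion
  set.seed(deriveSeed(p$seed, 2L))
  L <- p$nLoci
  draws <- matrix(p$loci$muR, nrows, L, byrow = TRUE) *
    matrix(rlnorm(nrows * L, -noiseSd^2 / 2, noiseSd), nrows, L)
  draws <- draws / rowMeans(draws)
  tab <- as.data.frame(draws)
  names(tab) <- p$loci$locus
  PosteriorTable("rates", tab)
}

#' Pseudo-posterior of demographic parameters
#'
#' Correlated draws around the scenario truths: a Gaussian copula on the
#' log scale (logit scale for the founding fraction s) with exchangeable
#' correlation `corr` and marginal spread `dispersion`.  With
#' `dispersion = 0` every row equals the truth.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param source `"lamarc"`, `"im"`, `"fd"` or `"recomb"`.
#' @param nrows number of draws.
#' @param dispersion marginal sdlog; defaults to the scenario setting.
#' @param corr pairwise correlation of the underlying Gaussians.
#' @return a [PosteriorTable-class] of the requested dialect.
#' @export
genHistoryPosterior <- function(scenario, source = c("lamarc", "im", "fd",
                                                     "recomb"),
                                nrows = 2000, dispersion = NULL,
                                corr = 0.3) {
  source <- match.arg(source)
  p <- scenario@params
  if (is.null(dispersion)) dispersion <- p$dispersion
  set.seed(deriveSeed(p$seed, 3L + match(source, c("lamarc", "im", "fd",
                                                   "recomb"))))
  if (source == "recomb") {
    L <- p$nLoci
    draws <- matrix(p$loci$recomb, nrows, L, byrow = TRUE) *
      matrix(rlnorm(nrows * L, -dispersion^2 / 2, dispersion), nrows, L)
    tab <- as.data.frame(draws)
    names(tab) <- p$loci$locus
    return(PosteriorTable("recomb", tab))
  }
  truth <- switch(source, lamarc = p$twoIsland, im = p$im, fd = p$fd)
  if (source == "lamarc") truth$r <- mean(p$loci$recomb)
  k <- length(truth)
  common <- rnorm(nrows)
  z <- sqrt(corr) * matrix(common, nrows, k) +
    sqrt(1 - corr) * matrix(rnorm(nrows * k), nrows, k)
  tab <- as.data.frame(matrix(0, nrows, k))
  names(tab) <- names(truth)
  for (j in seq_len(k)) {
    nm <- names(truth)[j]
    if (nm == "s") {
      # logit-normal around truth, kept inside (0, 1)
      lo <- log(truth$s / (1 - truth$s)) + dispersion * 2 * z[, j]
      tab[[j]] <- 1 / (1 + exp(-lo))
    } else {
      tab[[j]] <- truth[[nm]] * exp(dispersion * z[, j] -
                                      dispersion^2 / 2)
    }
  }
  PosteriorTable(source, tab)
}

#' Simulate a full multilocus dataset under the scenario truth
#'
#' Generates one alignment per locus by coalescent simulation at the truth
#' parameters and realizes nucleotide sequences.  The default `"panmictic"`
#' model pools both populations into one deme (locus theta = theta_site *
#' L * muR * ploidy), which is the regime where the Watterson estimator is
#' exactly unbiased and therefore the one used for estimator-recovery
#' checks; `"isolation_migration"` and `"two_island"` generate structured
#' data under the corresponding truth demography.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param model `"panmictic"`, `"two_island"` or `"isolation_migration"`.
#' @param seed seed for this dataset (so repeated datasets differ while
#'   the scenario truth stays fixed).
#' @param realize return sequences (TRUE) or segregating-site objects only.
#' @return list with `alignments` (list of [LocusAlignment-class] or
#'   [SimulatedLocus-class]), `popmap` (data.frame), `stats` (per-locus
#'   [locusStats()] rows), `truth` (per-locus theta and expected S).
#' @export
genMultilocusDataset <- function(scenario, model = "panmictic",
                                 seed = scenario@params$seed,
                                 realize = TRUE) {
  p <- scenario@params
  loci <- p$loci
  nPer <- p$nPerDeme
  dem <- switch(model,
    panmictic = DemographicModel("pop", sizes = 1,
                                 thetaSite = p$thetaSite,
                                 modelType = "panmictic"),
    two_island = buildTwoIsland(p$twoIsland),
    isolation_migration = buildIsolationMigration(p$im,
                                                  .geomean(loci$length)),
    stop("unknown model ", model))
  nSamp <- if (model == "panmictic") sum(nPer) else nPer
  alns <- vector("list", nrow(loci))
  statsRows <- vector("list", nrow(loci))
  thetaLocus <- numeric(nrow(loci))
  for (l in seq_len(nrow(loci))) {
    set.seed(deriveSeed(seed, 100L + l))
    spec <- LocusSimSpec(loci$locus[l], loci$length[l], muR = loci$muR[l],
                         rhoLocus = loci$recomb[l] * p$thetaSite *
                           loci$muR[l] * (loci$length[l] - 1),
                         ploidyFactor = loci$ploidy[l])
    sim <- simulateLocus(dem, spec, nSamp, returnMatrix = realize)
    thetaLocus[l] <- p$thetaSite * loci$length[l] * loci$muR[l] *
      loci$ploidy[l]
    if (realize) {
      aln <- realizeSequences(sim)
      names(aln@sequences) <- sprintf("a%03d", seq_along(aln@sequences))
      alns[[l]] <- aln
      statsRows[[l]] <- locusStats(aln)
    } else {
      alns[[l]] <- sim
      statsRows[[l]] <- simulatedLocusStats(sim)
    }
  }
  n <- if (model == "panmictic") sum(nPer) else sum(nPer)
  popLabs <- if (model == "panmictic") rep("pop", n) else
    rep(dem@demeNames[1:2], nPer)
  truth <- data.frame(locus = loci$locus, thetaLocus = thetaLocus,
                      expectedS = thetaLocus * .hkaA(n),
                      stringsAsFactors = FALSE)
  list(alignments = alns,
       popmap = data.frame(sample = sprintf("a%03d", seq_len(n)),
                           population = popLabs,
                           stringsAsFactors = FALSE),
       stats = do.call(rbind, statsRows), truth = truth)
}

#' Synthetic HKA inputs with optional planted sweep
#'
#' Segregating sites are simulated panmictically at the per-locus truth
#' theta; divergence counts are Poisson with mean
#' `2 * divergence * L * muR` (the split-time substitutions) plus, when
#' `ancestral = TRUE`, a per-comparison exponential ancestral-coalescent
#' contribution `theta_locus * Exp(1)` -- the lineage-sorting variance the
#' HKA model expects.  A planted sweep suppresses one locus's polymorphism
#' by simulating it at theta / `plantedFactor` while leaving its
#' divergence untouched.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param divergence per-site split-time divergence (substitutions/site)
#'   for each outgroup; its length sets the number of outgroups.
#' @param nWithin sampled alleles within the focal species.
#' @param ancestral include the ancestral lineage-sorting contribution.
#' @param planted index of a swept locus (NULL for none).
#' @param plantedFactor polymorphism suppression factor.
#' @param seed seed.
#' @return list of data.frames (one per outgroup) as for [hkaTest()].
#' @export
genHKAInputs <- function(scenario, divergence = 0.1, nWithin = 50,
                         ancestral = TRUE, planted = NULL,
                         plantedFactor = 10, seed = scenario@params$seed) {
  p <- scenario@params
  loci <- p$loci
  L <- nrow(loci)
  dem <- DemographicModel("pop", sizes = 1, thetaSite = p$thetaSite,
                          modelType = "panmictic")
  thetaLocus <- p$thetaSite * loci$length * loci$muR * loci$ploidy
  set.seed(deriveSeed(seed, 7L))
  S <- integer(L)
  for (l in seq_len(L)) {
    mult <- if (!is.null(planted) && l == planted) 1 / plantedFactor else 1
    spec <- LocusSimSpec(loci$locus[l], loci$length[l],
                         muR = loci$muR[l] * mult,
                         rhoLocus = 0, ploidyFactor = loci$ploidy[l])
    sim <- simulateLocus(dem, spec, nWithin, returnMatrix = FALSE)
    S[l] <- length(sim@positions)
  }
  lapply(seq_along(divergence), function(o) {
    dmean <- 2 * divergence[o] * loci$length * loci$muR
    if (ancestral) dmean <- dmean + thetaLocus * rexp(L)
    data.frame(locus = loci$locus, n_within = nWithin, L = loci$length,
               S_within = S, D_out = rpois(L, dmean),
               outgroup = sprintf("outgroup%02d", o),
               stringsAsFactors = FALSE)
  })
}

#' Packaged per-locus empirical summary table
#'
#' The 22-locus panel of published per-locus statistics shipped with the
#' package (tab-separated under `inst/extdata`), used as the empirical
#' input of the worked examples and tests: locus abbreviation, fragment
#' length (bp), nucleotide diversity, Phi-ST and Tajima's D (averaged
#' between the two populations).
#'
#' @return data.frame with columns `locus`, `length_bp`, `pi`, `phi_st`,
#'   `tajd`.
#' @export
table1Fixture <- function() {
  readTable1(system.file("extdata", "table1_loci.tsv", package = "coalfit",
                         mustWork = TRUE))
}

#' Write a synthetic dataset to disk
#'
#' FASTA per locus, a two-column popmap, per-locus statistics and the
#' truth table, for running the pipeline from files.
#'
#' @param dataset output of [genMultilocusDataset()] with `realize = TRUE`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (aln in dataset$alignments)
    writeLocusFasta(aln, file.path(dir, paste0(locusId(aln), ".fasta")))
  utils::write.table(dataset$popmap, file.path(dir, "popmap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$stats, file.path(dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
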