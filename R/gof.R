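#' Counter-derived child seeds
#'
#' Derives a reproducible child seed from a root seed and a counter (kept
#' below 2^31), so that any (history, locus) simulation cell -- or any
#' trial of a calibration experiment -- can be re-run in isolation.
#'
#' @param root integer root seed.
#' @param counter integer stream counter.
#' @return an integer seed.
#' @export
deriveSeed <- function(root, counter) {
  as.integer((as.double(root) * 48271 + as.double(counter) * 16807) %%
               2147483629)
}

#' Posterior predictive distributions of summary statistics
#'
#' Simulates every locus under every assembled history, computes per-locus
#' nucleotide diversity, Phi-ST and Tajima's D (averaged between the two
#' sampled populations), and stores both the full histories x loci
#' matrices and the per-history dataset-level means and coefficients of
#' variation.  Replicates where a statistic is undefined (e.g. Tajima's D
#' with no segregating sites) are excluded from that locus's predictive
#' column and counted.
#'
#' @param histories a [HistorySet-class].
#' @param nPerDeme sampled alleles per population (default 50 and 50,
#'   mirroring 25 diploids per population).
#' @param seed root seed; per-(history, locus) streams are derived by
#'   counter so any single cell can be re-simulated in isolation.
#' @param lociSubset optional character vector restricting simulation to a
#'   subset of the panel (used by the selection-subset model).
#' @return a [PredictiveDistribution-class].
#' @export
posteriorPredictive <- function(histories, nPerDeme = c(50, 50), seed = 1L,
                                lociSubset = NULL) {
  stopifnot(is(histories, "HistorySet"))
  loci <- histories@loci
  keep <- if (is.null(lociSubset)) seq_len(nrow(loci)) else {
    miss <- setdiff(lociSubset, loci$locus)
    if (length(miss)) stop("unknown loci in subset: ",
                           paste(miss, collapse = ", "))
    match(lociSubset, loci$locus)
  }
  n <- nHistories(histories)
  L <- length(keep)
  piM <- matrix(NA_real_, n, L)
  phiM <- matrix(NA_real_, n, L)
  tdM <- matrix(NA_real_, n, L)
  sM <- matrix(NA_real_, n, L)
  for (h in seq_len(n)) {
    model <- historyModel(histories, h)
    nd <- length(model@demeNames)
    nSamp <- c(as.integer(nPerDeme), integer(max(0, nd - length(nPerDeme))))
    ev <- model@events
    evKind <- .eventCodes[ev$kind]
    for (li in seq_len(L)) {
      l <- keep[li]
      set.seed(deriveSeed(seed, (h - 1) * nrow(loci) + l))
      theta <- model@thetaSite * loci$length[l] * histories@muR[h, l] *
        loci$ploidy[l]
      rho <- histories@rho[h, l] * model@thetaSite * histories@muR[h, l] *
        (loci$length[l] - 1) * loci$ploidy[l]
      res <- sim_locus_cpp(nSamp, model@sizes, model@growth,
                           model@migration, as.numeric(ev$time), evKind,
                           as.integer(ev$deme), as.integer(ev$deme2),
                           as.numeric(ev$value), theta, rho, FALSE)
      sampled <- nSamp > 0L
      st <- counts_stats_cpp(res$counts[, sampled, drop = FALSE],
                             nSamp[sampled], loci$length[l])
      piM[h, li] <- st[1]
      phiM[h, li] <- st[2]
      tdM[h, li] <- st[3]
      sM[h, li] <- st[4]
    }
  }
  colnames(piM) <- colnames(phiM) <- colnames(tdM) <- colnames(sM) <-
    loci$locus[keep]
  rowCV <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    sdv <- apply(m, 1, sd, na.rm = TRUE)
    sdv / abs(mu)
  }
  means <- data.frame(pi = rowMeans(piM, na.rm = TRUE),
                      phi_st = rowMeans(phiM, na.rm = TRUE),
                      tajd = rowMeans(tdM, na.rm = TRUE))
  cvs <- data.frame(pi = rowCV(piM), phi_st = rowCV(phiM),
                    tajd = rowCV(tdM))
  undef <- data.frame(locus = loci$locus[keep],
                      pi = colSums(is.na(piM)),
                      phi_st = colSums(is.na(phiM)),
                      tajd = colSums(is.na(tdM)))
  new("PredictiveDistribution", pi = piM, phiSt = phiM, tajd = tdM, S = sM,
      lociIds = loci$locus[keep], datasetMeans = means, datasetCVs = cvs,
      undefinedCounts = undef, seed = as.numeric(seed),
      modelType = histories@modelType)
}

setMethod("show", "PredictiveDistribution", function(object) {
  cat("PredictiveDistribution [", object@modelType, "]: ",
      nrow(object@pi), " histories x ", ncol(object@pi), " loci\n",
      sep = "")
  cat("  dataset-level mean pi: median ",
      signif(stats::median(object@datasetMeans$pi, na.rm = TRUE), 4),
      ", CV(pi): median ",
      signif(stats::median(object@datasetCVs$pi, na.rm = TRUE), 4), "\n",
      sep = "")
})

# two-tailed empirical-quantile p with plug-in floor 2/n (a finite set of
# simulations cannot support p = 0) and cap 1
.tailP <- function(obs, sims) {
  sims <- sims[!is.na(sims)]
  n <- length(sims)
  if (n == 0L) return(NA_real_)
  p <- 2 * min(sum(sims <= obs), sum(sims >= obs)) / n
  min(1, max(2 / n, p))
}

#' Dataset-level goodness-of-fit tests
#'
#' Compares empirical dataset-level values (the cross-locus mean and
#' coefficient of variation of nucleotide diversity, Phi-ST and Tajima's D)
#' with their posterior predictive distributions.  The two-tailed p-value
#' is `2 * min(#sim <= obs, #sim >= obs) / n`, floored at `2/n` and capped
#' at 1; values inside the 2.5% tails are significant at `alpha = 0.05`.
#'
#' @param empirical either a [multilocusSummary()] data.frame or a
#'   per-locus statistics data.frame (from which the summary is computed).
#' @param predictive a [PredictiveDistribution-class] with >= 100
#'   histories.
#' @param alpha significance level.
#' @return a [GOFResult-class] whose table has one row per test (mean and
#'   CV of each statistic).
#' @export
gofDataset <- function(empirical, predictive, alpha = 0.05) {
  stopifnot(is(predictive, "PredictiveDistribution"))
  n <- nrow(predictive@pi)
  if (n < 100) stop("predictive distribution needs >= 100 histories")
  if (!all(c("statistic", "mean", "cv") %in% names(empirical)))
    empirical <- multilocusSummary(empirical)
  rows <- list()
  for (stat in c("pi", "phi_st", "tajd")) {
    er <- empirical[empirical$statistic == stat, ]
    if (nrow(er) != 1L || is.na(er$mean))
      stop("empirical summary lacks statistic ", stat)
    for (what in c("mean", "cv")) {
      obs <- er[[what]]
      sims <- if (what == "mean") predictive@datasetMeans[[stat]] else
        predictive@datasetCVs[[stat]]
      p <- .tailP(obs, sims)
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = stat, measure = what, empirical = obs, p = p,
        significant = !is.na(p) & p <= alpha, stringsAsFactors = FALSE)
    }
  }
  new("GOFResult", table = do.call(rbind, rows), level = "dataset",
      alpha = alpha, nHistories = n)
}

#' Locus-specific goodness-of-fit tests with FDR control
#'
#' Per-locus two-tailed empirical-quantile p-values against each locus's
#' predictive column, corrected across loci by the Benjamini-Hochberg
#' step-up procedure at level `q`.
#'
#' @param empirical data.frame with a `locus` column and per-locus
#'   statistic columns (`pi`, and optionally `phi_st`, `tajd`).
#' @param predictive a [PredictiveDistribution-class].
#' @param q FDR level.
#' @param statistics which statistics to test.
#' @return a [GOFResult-class]; table columns `locus`, `statistic`,
#'   `empirical`, `p`, `p_bh`, `significant`.
#' @export
gofLocusFdr <- function(empirical, predictive, q = 0.05,
                        statistics = c("pi", "phi_st", "tajd")) {
  stopifnot(is(predictive, "PredictiveDistribution"))
  statistics <- intersect(statistics, names(empirical))
  if (!length(statistics)) stop("no statistic columns found in empirical")
  miss <- setdiff(empirical$locus, predictive@lociIds)
  if (length(miss))
    stop("loci missing from the predictive distribution: ",
         paste(miss, collapse = ", "))
  slotOf <- c(pi = "pi", phi_st = "phiSt", tajd = "tajd")
  out <- list()
  for (stat in statistics) {
    simM <- slot(predictive, slotOf[[stat]])
    p <- vapply(seq_len(nrow(empirical)), function(i) {
      .tailP(empirical[[stat]][i],
             simM[, as.character(empirical$locus[i])])
    }, numeric(1))
    pbh <- p.adjust(p, method = "BH")
    out[[stat]] <- data.frame(
      locus = empirical$locus, statistic = stat,
      empirical = empirical[[stat]], p = p, p_bh = pbh,
      significant = !is.na(pbh) & pbh <= q, stringsAsFactors = FALSE)
  }
  new("GOFResult", table = do.call(rbind, out), level = "locus",
      alpha = q, nHistories = nrow(predictive@pi))
}

setMethod("show", "GOFResult", function(object) {
  cat("GOFResult (", object@level, "-level, ", object@nHistories,
      " histories, alpha/q = ", object@alpha, ")\n", sep = "")
  tab <- object@table
  if (object@level == "dataset") print(tab, row.names = FALSE)
  else {
    sig <- tab[tab$significant, ]
    cat("  ", nrow(tab), " tests, ", nrow(sig),
        " significant after FDR correction\n", sep = "")
    if (nrow(sig)) print(sig, row.names = FALSE)
  }
})
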