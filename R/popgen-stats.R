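#' @useDynLib coalfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats density pchisq quantile rbinom rlnorm rnorm rpois runif
#'   sd setNames uniroot var p.adjust rexp qnorm
#' @importFrom utils read.delim write.table
NULL

# character matrix of the alignment with every column containing a gap or
# ambiguity removed (complete deletion; mirrors the rule that gapped regions
# are excluded from all statistics)
.cleanMatrix <- function(aln) {
  m <- as.matrix(aln@sequences)
  if (ncol(m) == 0L) return(m)
  bad <- colSums(m == "-" | m == "N" | m == "n") > 0
  m[, !bad, drop = FALSE]
}

.nPairs <- function(n) n * (n - 1) / 2

# per-column derived/allele accounting: total pairwise differences summed
# over columns via allele counts (exact, O(nL))
.pairDiffTotal <- function(m) {
  if (ncol(m) == 0L) return(0)
  n <- nrow(m)
  tot <- 0
  for (b in unique(as.vector(m))) {
    cnt <- colSums(m == b)
    tot <- tot + sum(cnt * (n - cnt))
  }
  tot / 2
}

# number of segregating (polymorphic) columns
.countSegSites <- function(m) {
  if (ncol(m) == 0L) return(0L)
  sum(apply(m, 2, function(col) length(unique(col)) > 1L))
}

#' Nucleotide diversity per site
#'
#' Mean number of pairwise differences per analysed site, computed after
#' complete deletion of every column containing a gap (`-`) or `N`.
#'
#' @param aln a [LocusAlignment-class] with at least two sequences.
#' @return numeric with attribute `nSitesUsed`, the number of surviving
#'   columns.
#' @export
nucleotideDiversity <- function(aln) {
  stopifnot(is(aln, "LocusAlignment"))
  if (length(aln) < 2L) stop("need at least 2 sequences")
  m <- .cleanMatrix(aln)
  if (ncol(m) == 0L)
    stop("no usable columns after removing gapped sites in locus ",
         aln@locusId)
  pi <- .pairDiffTotal(m) / .nPairs(nrow(m)) / ncol(m)
  attr(pi, "nSitesUsed") <- ncol(m)
  pi
}

# Tajima (1989) constants for sample size n
.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajimaD <- function(S, piTotal, n) {
  # piTotal = mean pairwise differences (per locus, not per site)
  if (S == 0L || n < 4L) return(NA_real_)
  k <- .tajimaConstants(n)
  (piTotal - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Standardised difference between the pairwise-diversity and
#' segregating-sites estimators of theta (Tajima 1989).  Undefined (NA)
#' when the selected sample has no segregating sites or fewer than four
#' sequences.  Gap columns are removed by complete deletion over the whole
#' alignment before any population is subset, so all populations are scored
#' on the same sites.
#'
#' @param aln a [LocusAlignment-class].
#' @param pop optional population label; default uses all sequences.
#' @return a single numeric (possibly NA).  When `pop` is NULL the result
#'   carries attributes `perPop` (named vector of per-population values) and
#'   `meanPerPop` (their mean over defined values).
#' @export
tajimasD <- function(aln, pop = NULL) {
  stopifnot(is(aln, "LocusAlignment"))
  m <- .cleanMatrix(aln)
  calc <- function(rows) {
    mm <- m[rows, , drop = FALSE]
    n <- nrow(mm)
    if (n < 4L) return(NA_real_)
    S <- .countSegSites(mm)
    if (S == 0L) return(NA_real_)
    piTot <- .pairDiffTotal(mm) / .nPairs(n)
    .tajimaD(S, piTot, n)
  }
  if (!is.null(pop)) {
    rows <- which(aln@popLabels == pop)
    if (!length(rows)) stop("no sequences labelled ", pop)
    return(calc(rows))
  }
  d <- calc(seq_len(nrow(m)))
  per <- vapply(levels(aln@popLabels),
                function(p) calc(which(aln@popLabels == p)), numeric(1))
  attr(d, "perPop") <- per
  attr(d, "meanPerPop") <-
    if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  d
}

# AMOVA variance partition on pairwise-difference distances for arbitrary
# group labels; returns Phi-ST (unclamped, may be negative)
.phiFromDiffs <- function(m, labels) {
  n <- nrow(m)
  groups <- split(seq_len(n), labels)
  P <- length(groups)
  ssTotal <- .pairDiffTotal(m) / n
  ssWithin <- sum(vapply(groups, function(rows) {
    if (length(rows) < 2L) return(0)
    .pairDiffTotal(m[rows, , drop = FALSE]) / length(rows)
  }, numeric(1)))
  ssAmong <- ssTotal - ssWithin
  dfAmong <- P - 1L
  dfWithin <- n - P
  sigmaW <- ssWithin / dfWithin
  nprime <- (n - sum(vapply(groups, length, numeric(1))^2) / n) / dfAmong
  sigmaA <- (ssAmong / dfAmong - sigmaW) / nprime
  denom <- sigmaA + sigmaW
  if (denom == 0) return(NA_real_)
  sigmaA / denom
}

#' Phi-ST with a permutation test
#'
#' AMOVA-style partition of molecular variance among versus within
#' populations using pairwise-difference distances between haplotypes (no
#' substitution-model correction).  Negative values are retained unclamped.
#' The p-value comes from permuting population labels.
#'
#' @param aln a [LocusAlignment-class] with >= 2 populations, each with >= 2
#'   sequences.
#' @param nPermutations number of label permutations (0 skips the test).
#' @return list with elements `phiSt` and `pValue` (NA when
#'   `nPermutations = 0` or the statistic is undefined).
#' @export
phiSt <- function(aln, nPermutations = 999) {
  stopifnot(is(aln, "LocusAlignment"))
  labels <- droplevels(aln@popLabels)
  if (nlevels(labels) < 2L) stop("need at least 2 populations")
  if (any(table(labels) < 2L))
    stop("every population needs at least 2 sequences")
  m <- .cleanMatrix(aln)
  if (ncol(m) == 0L)
    stop("no usable columns after removing gapped sites in locus ",
         aln@locusId)
  obs <- .phiFromDiffs(m, labels)
  p <- NA_real_
  if (!is.na(obs) && nPermutations > 0) {
    hits <- 0L
    for (b in seq_len(nPermutations)) {
      perm <- .phiFromDiffs(m, sample(labels))
      if (!is.na(perm) && perm >= obs) hits <- hits + 1L
    }
    p <- (hits + 1) / (nPermutations + 1)
  }
  list(phiSt = obs, pValue = p)
}

#' Per-locus summary statistics
#'
#' Bundles nucleotide diversity, Phi-ST, Tajima's D (total, per population,
#' and averaged between populations) and the number of segregating sites,
#' all computed on gap-deleted columns.
#'
#' @param aln a [LocusAlignment-class].
#' @param nPermutations permutations for the Phi-ST test (0 = skip).
#' @return a one-row data.frame with columns `locus`, `pi`, `phi_st`,
#'   `phi_p`, `tajd`, `tajd_mean`, per-population Tajima's D columns
#'   (`tajd_<pop>`), `S` and `n_sites_used`.
#' @export
locusStats <- function(aln, nPermutations = 0) {
  pi <- nucleotideDiversity(aln)
  m <- .cleanMatrix(aln)
  S <- .countSegSites(m)
  d <- tajimasD(aln)
  per <- attr(d, "perPop")
  labs <- droplevels(aln@popLabels)
  phiOk <- S > 0L && nlevels(labs) >= 2L && all(table(labs) >= 2L)
  phi <- if (phiOk) phiSt(aln, nPermutations) else
    list(phiSt = NA_real_, pValue = NA_real_)
  out <- data.frame(
    locus = aln@locusId,
    pi = as.numeric(pi),
    phi_st = phi$phiSt,
    phi_p = phi$pValue,
    tajd = as.numeric(d),
    tajd_mean = attr(d, "meanPerPop"),
    S = S,
    n_sites_used = attr(pi, "nSitesUsed"),
    stringsAsFactors = FALSE)
  for (p in names(per)) out[[paste0("tajd_", p)]] <- per[[p]]
  out
}

#' Cross-locus summary of per-locus statistics
#'
#' Mean, sample SD (n-1 denominator), coefficient of variation
#' (CV = SD / |mean|), minimum, maximum and counts for each statistic
#' across loci.  Undefined (NA) per-locus entries are excluded and counted.
#'
#' @param stats either a data.frame of per-locus statistics with columns
#'   `pi`, `phi_st` and a Tajima's D column (`tajd` or `tajd_mean`) -- e.g.
#'   rows of [locusStats()] or a table read by [readTable1()] -- or a list
#'   of such one-row data.frames.
#' @return data.frame with one row per statistic and columns `statistic`,
#'   `mean`, `sd`, `cv`, `min`, `max`, `n_loci`, `n_undefined`.
#' @export
multilocusSummary <- function(stats) {
  if (is.list(stats) && !is.data.frame(stats))
    stats <- do.call(rbind, stats)
  cols <- c(pi = "pi", phi_st = "phi_st",
            tajd = if ("tajd" %in% names(stats)) "tajd" else "tajd_mean")
  rows <- lapply(names(cols), function(nm) {
    v <- stats[[cols[[nm]]]]
    ok <- v[!is.na(v)]
    if (length(ok) < 2L)
      stop("statistic ", nm, " has fewer than 2 defined values")
    data.frame(statistic = nm, mean = mean(ok), sd = sd(ok),
               cv = sd(ok) / abs(mean(ok)),
               min = min(ok), max = max(ok),
               n_loci = length(ok), n_undefined = sum(is.na(v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a per-locus summary-statistics table
#'
#' Tab-separated dialect with header columns `locus`, `length_bp`, `pi`,
#' `phi_st`, `tajd` (UTF-8, '.' decimal separator).
#'
#' @param path path to the TSV file.
#' @return data.frame of per-locus empirical statistics.
#' @export
readTable1 <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "length_bp", "pi", "phi_st", "tajd")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("summary table is missing columns: ", paste(missing, collapse = ", "))
  for (col in c("length_bp", "pi", "phi_st", "tajd"))
    if (!is.numeric(tab[[col]]))
      stop("column ", col, " must be numeric")
  tab
}
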