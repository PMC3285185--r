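#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Phased multilocus alignment for a single locus
#'
#' Container for the phased allele sequences of one locus together with the
#' population label of every allele, the reference fragment length used for
#' per-site scaling, and the ploidy factor (1 for autosomal loci, 0.75 for
#' Z-linked loci, reflecting the reduced effective copy number of sex-linked
#' sequence).
#'
#' @slot locusId single character identifier.
#' @slot sequences a [Biostrings::DNAStringSet] of equal-width sequences over
#'   the alphabet A, C, G, T, `-`, N.
#' @slot popLabels factor of population labels, one per sequence.
#' @slot fragmentLength integer, ungapped reference span in bp used when
#'   expressing statistics per site.
#' @slot ploidyFactor numeric in (0, 1].
#'
#' @exportClass LocusAlignment
setClass("LocusAlignment",
  representation(
    locusId = "character",
    sequences = "DNAStringSet",
    popLabels = "factor",
    fragmentLength = "integer",
    ploidyFactor = "numeric"
  )
)

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L) msg <- c(msg, "locusId must be length 1")
  w <- Biostrings::width(object@sequences)
  if (length(w) == 0L) msg <- c(msg, "alignment contains no sequences")
  if (length(unique(w)) > 1L) msg <- c(msg, "sequences have unequal lengths")
  if (length(object@popLabels) != length(object@sequences))
    msg <- c(msg, "popLabels must match the number of sequences")
  if (length(object@fragmentLength) != 1L || is.na(object@fragmentLength) ||
      object@fragmentLength < 1L)
    msg <- c(msg, "fragmentLength must be a positive integer")
  if (length(object@ploidyFactor) != 1L || object@ploidyFactor <= 0 ||
      object@ploidyFactor > 1)
    msg <- c(msg, "ploidyFactor must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Demographic model in simulator (ms) units
#'
#' A set of demes with present-day relative sizes and exponential growth
#' rates, a backward-time migration matrix, and a time-ordered list of
#' demographic events.  Units follow the ms conventions: time is measured in
#' units of 4*N0 generations where N0 is the present effective size of the
#' first (anchor) deme; deme sizes are relative to N0; `migration[i, j]` is
#' the backward per-lineage rate 4*N0*m_ij at which lineages currently in
#' deme i trace their ancestry to deme j.  The `thetaSite` slot records the
#' per-site population mutation parameter 4*N0*mu of the anchor deme (on the
#' across-locus mean-rate scale) so that locus-level theta can be formed as
#' thetaSite * L * muR * ploidy.
#'
#' @slot demeNames character vector of deme names; the first deme anchors N0.
#' @slot sizes numeric, present-day sizes relative to N0.
#' @slot growth numeric backward growth rates (ms `-g` convention: deme size
#'   at time t pastward is `size * exp(-growth * t)`).
#' @slot migration square numeric matrix of backward rates, zero diagonal.
#' @slot events data.frame with columns `time`, `kind` (one of
#'   `"size_change"`, `"growth_change"`, `"split_join"`,
#'   `"migration_change"`), `deme`, `deme2`, `value`, sorted by time.
#' @slot thetaSite per-site theta of the anchor deme.
#' @slot modelType character tag (e.g. `"two_island"`).
#'
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(
    demeNames = "character",
    sizes = "numeric",
    growth = "numeric",
    migration = "matrix",
    events = "data.frame",
    thetaSite = "numeric",
    modelType = "character"
  )
)

.eventKinds <- c("size_change", "growth_change", "split_join",
                 "migration_change")

setValidity("DemographicModel", function(object) {
  msg <- character()
  nd <- length(object@demeNames)
  if (length(object@sizes) != nd || length(object@growth) != nd)
    msg <- c(msg, "sizes and growth must have one entry per deme")
  if (any(object@sizes <= 0)) msg <- c(msg, "deme sizes must be positive")
  if (!all(dim(object@migration) == c(nd, nd)))
    msg <- c(msg, "migration must be a square deme x deme matrix")
  if (any(object@migration < 0)) msg <- c(msg, "migration rates must be >= 0")
  ev <- object@events
  need <- c("time", "kind", "deme", "deme2", "value")
  if (!all(need %in% names(ev)))
    msg <- c(msg, "events must have columns time, kind, deme, deme2, value")
  else {
    if (nrow(ev) && is.unsorted(ev$time))
      msg <- c(msg, "events must be sorted by time")
    if (nrow(ev) && !all(ev$kind %in% .eventKinds))
      msg <- c(msg, "unknown event kind")
    if (nrow(ev) && any(ev$time < 0)) msg <- c(msg, "event times must be >= 0")
  }
  if (length(object@thetaSite) != 1L || object@thetaSite < 0)
    msg <- c(msg, "thetaSite must be a single non-negative number")
  if (length(msg) == 0L && !.ancestryReachable(object))
    msg <- c(msg, paste("lineages cannot reach a common ancestor:",
                        "isolated demes with no migration or join events"))
  if (length(msg)) msg else TRUE
})

# Conservative reachability check: demes must form one connected component
# under the union of all positive migration rates (initial matrix plus any
# migration_change with value > 0) and all split_join events.
.ancestryReachable <- function(model) {
  nd <- length(model@demeNames)
  if (nd == 1L) return(TRUE)
  adj <- (model@migration > 0)
  ev <- model@events
  if (nrow(ev)) {
    for (r in seq_len(nrow(ev))) {
      if (ev$kind[r] == "migration_change" && ev$value[r] > 0)
        adj[ev$deme[r], ev$deme2[r]] <- TRUE
      if (ev$kind[r] == "split_join")
        adj[ev$deme[r], ev$deme2[r]] <- TRUE
    }
  }
  adj <- adj | t(adj)
  seen <- c(TRUE, rep(FALSE, nd - 1L))
  repeat {
    new <- seen | apply(adj[seen, , drop = FALSE], 2, any)
    if (all(new == seen)) break
    seen <- new
  }
  all(seen)
}

#' Per-locus simulation specification
#'
#' Locus-level inputs for [simulateLocus()]: fragment length, relative
#' substitution rate, locus-scaled recombination rate and ploidy factor.
#' The effective locus mutation parameter is
#' `thetaSite(model) * fragmentLength * muR * ploidyFactor`, and the
#' effective recombination parameter is `rhoLocus * ploidyFactor`.
#'
#' @exportClass LocusSimSpec
setClass("LocusSimSpec",
  representation(
    locusId = "character",
    fragmentLength = "integer",
    muR = "numeric",
    rhoLocus = "numeric",
    ploidyFactor = "numeric"
  )
)

setValidity("LocusSimSpec", function(object) {
  msg <- character()
  if (object@fragmentLength < 1L) msg <- c(msg, "fragmentLength must be >= 1")
  if (object@muR <= 0) msg <- c(msg, "muR must be > 0")
  if (object@rhoLocus < 0) msg <- c(msg, "rhoLocus must be >= 0")
  if (object@ploidyFactor <= 0 || object@ploidyFactor > 1)
    msg <- c(msg, "ploidyFactor must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulated segregating-site data for one locus
#'
#' Output of [simulateLocus()]: the infinite-sites segregating-site matrix
#' (rows = sampled alleles, columns = sites with positions in [0, 1)),
#' per-deme derived-allele counts, the deme of origin of every row, and the
#' time to the most recent common ancestor in units of 4*N0 generations.
#'
#' @exportClass SimulatedLocus
setClass("SimulatedLocus",
  representation(
    locusId = "character",
    matrix = "matrix",
    positions = "numeric",
    counts = "matrix",
    demes = "factor",
    tmrca = "numeric",
    fragmentLength = "integer"
  )
)

setValidity("SimulatedLocus", function(object) {
  msg <- character()
  if (ncol(object@matrix) != length(object@positions))
    msg <- c(msg, "column count must equal the number of segregating sites")
  if (nrow(object@matrix) != length(object@demes) && nrow(object@matrix) > 0)
    msg <- c(msg, "row count must match deme labels")
  if (length(msg)) msg else TRUE
})

#' Validated posterior-sample table
#'
#' A table of posterior draws in one of four dialects: `lamarc`
#' (per-site-scaled Theta and M plus a per-site relative recombination
#' rate), `im` (per-locus-scaled theta, migration, divergence time and
#' founding proportion), `rates` (per-locus relative substitution rates,
#' each row constrained to mean 1), or `recomb` (per-locus relative
#' recombination rates).
#'
#' @exportClass PosteriorTable
setClass("PosteriorTable",
  representation(
    source = "character",
    table = "data.frame",
    scaling = "character"
  )
)

setValidity("PosteriorTable", function(object) {
  msg <- character()
  if (!object@source %in% c("lamarc", "im", "rates", "recomb", "fd"))
    msg <- c(msg, "source must be one of lamarc, im, rates, recomb, fd")
  tab <- object@table
  if (nrow(tab) == 0L) msg <- c(msg, "posterior table is empty")
  if (!all(vapply(tab, is.numeric, logical(1))))
    msg <- c(msg, "all posterior columns must be numeric")
  else if (!all(is.finite(as.matrix(tab))))
    msg <- c(msg, "all posterior draws must be finite")
  if (object@source == "rates" && nrow(tab)) {
    rm <- rowMeans(as.matrix(tab))
    if (any(abs(rm - 1) > 1e-6))
      msg <- c(msg, sprintf(
        "rates rows must average 1 across loci (worst row mean %.4f)",
        rm[which.max(abs(rm - 1))]))
  }
  if (length(msg)) msg else TRUE
})

#' A set of assembled simulation histories
#'
#' Joint parameter draws for posterior predictive simulation: one
#' demographic draw per history plus per-locus relative substitution rates,
#' recombination rates, fragment lengths and ploidy factors, together with
#' model-specific extras (bottleneck times and recovery sizes, or
#' third-population hybridization draws).
#'
#' @exportClass HistorySet
setClass("HistorySet",
  representation(
    modelType = "character",
    draws = "data.frame",
    muR = "matrix",
    rho = "matrix",
    loci = "data.frame",
    extras = "list",
    geomeanL = "numeric",
    seed = "numeric",
    provenance = "list"
  )
)

setValidity("HistorySet", function(object) {
  msg <- character()
  n <- nrow(object@draws)
  L <- nrow(object@loci)
  if (!object@modelType %in% c("two_island", "isolation_migration",
                               "bottleneck", "hybridization"))
    msg <- c(msg, "unknown modelType")
  if (nrow(object@muR) != n || nrow(object@rho) != n)
    msg <- c(msg, "muR and rho must have one row per history")
  if (ncol(object@muR) != L || ncol(object@rho) != L)
    msg <- c(msg, "muR and rho must have one column per locus")
  if (!all(c("locus", "length", "ploidy") %in% names(object@loci)))
    msg <- c(msg, "loci must have columns locus, length, ploidy")
  if (object@modelType == "bottleneck" &&
      !all(c("tB", "thetaOwLamarc") %in% names(object@extras)))
    msg <- c(msg, "bottleneck histories need extras$tB and extras$thetaOwLamarc")
  if (object@modelType == "hybridization" && is.null(object@extras$fd))
    msg <- c(msg, "hybridization histories need extras$fd")
  if (length(msg)) msg else TRUE
})

#' Posterior predictive distributions of summary statistics
#'
#' Matrices of simulated per-locus statistics (histories x loci) for
#' nucleotide diversity, Phi-ST and Tajima's D, with per-history
#' dataset-level means and coefficients of variation and bookkeeping for
#' replicates where a statistic is undefined.
#'
#' @exportClass PredictiveDistribution
setClass("PredictiveDistribution",
  representation(
    pi = "matrix",
    phiSt = "matrix",
    tajd = "matrix",
    S = "matrix",
    lociIds = "character",
    datasetMeans = "data.frame",
    datasetCVs = "data.frame",
    undefinedCounts = "data.frame",
    seed = "numeric",
    modelType = "character"
  )
)

setValidity("PredictiveDistribution", function(object) {
  msg <- character()
  n <- nrow(object@pi)
  L <- ncol(object@pi)
  for (slotName in c("phiSt", "tajd", "S")) {
    m <- slot(object, slotName)
    if (nrow(m) != n || ncol(m) != L)
      msg <- c(msg, sprintf("%s matrix dimensions disagree with pi", slotName))
  }
  if (length(object@lociIds) != L)
    msg <- c(msg, "lociIds must have one entry per locus")
  if (nrow(object@datasetMeans) != n || nrow(object@datasetCVs) != n)
    msg <- c(msg, "dataset-level vectors must have one row per history")
  if (length(msg)) msg else TRUE
})

#' Goodness-of-fit test result
#'
#' @exportClass GOFResult
setClass("GOFResult",
  representation(
    table = "data.frame",
    level = "character",
    alpha = "numeric",
    nHistories = "numeric"
  )
)

#' Multilocus HKA test result
#'
#' @exportClass HKAResult
setClass("HKAResult",
  representation(
    theta = "numeric",
    Tdiv = "numeric",
    cells = "data.frame",
    contributions = "numeric",
    X2 = "numeric",
    df = "numeric",
    pValue = "numeric"
  )
)

setValidity("HKAResult", function(object) {
  msg <- character()
  if (abs(sum(object@contributions) - object@X2) > 1e-8 * max(1, object@X2))
    msg <- c(msg, "per-locus contributions must sum to X2")
  if (object@df != length(object@theta) - 1L)
    msg <- c(msg, "df must equal number of loci minus 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic study scenario
#'
#' Ground-truth parameters for the synthetic-data generators: the locus
#' panel (ids, fragment lengths, one Z-linked locus), per-locus relative
#' substitution-rate truths normalised to mean 1, recombination truths,
#' demographic truths for each model, pseudo-posterior dispersion settings
#' and the seed from which everything regenerates deterministically.
#'
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  representation(params = "list")
)
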