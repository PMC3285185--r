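#' Construct a DemographicModel
#'
#' Low-level constructor; most users should use the builders
#' [buildTwoIsland()], [buildIsolationMigration()], [buildBottleneck()] or
#' [buildHybridization()].  See [DemographicModel-class] for the unit
#' conventions.
#'
#' @param demeNames character vector; the first deme anchors N0.
#' @param sizes present-day deme sizes relative to N0.
#' @param growth backward exponential growth rates.
#' @param migration backward per-lineage rate matrix (4*N0*m).
#' @param events data.frame of demographic events (may be empty).
#' @param thetaSite per-site theta of the anchor deme.
#' @param modelType character tag.
#' @return a [DemographicModel-class].
#' @export
DemographicModel <- function(demeNames, sizes, growth = NULL,
                             migration = NULL, events = NULL,
                             thetaSite = 0, modelType = "custom") {
  nd <- length(demeNames)
  if (is.null(growth)) growth <- rep(0, nd)
  if (is.null(migration)) migration <- matrix(0, nd, nd)
  if (is.null(events)) events <- emptyEvents()
  diag(migration) <- 0
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  new("DemographicModel", demeNames = demeNames, sizes = as.numeric(sizes),
      growth = as.numeric(growth), migration = migration, events = events,
      thetaSite = as.numeric(thetaSite), modelType = modelType)
}

#' @rdname DemographicModel
#' @export
emptyEvents <- function() {
  data.frame(time = numeric(), kind = character(), deme = integer(),
             deme2 = integer(), value = numeric(), stringsAsFactors = FALSE)
}

.event <- function(time, kind, deme, deme2 = deme, value = 0) {
  data.frame(time = time, kind = kind, deme = deme, deme2 = deme2,
             value = value, stringsAsFactors = FALSE)
}

#' @rdname DemographicModel-class
#' @export
setMethod("thetaSite", "DemographicModel", function(x) x@thetaSite)

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel [", object@modelType, "], ",
      length(object@demeNames), " demes (anchor: ", object@demeNames[1],
      ", theta_site = ", signif(object@thetaSite, 4), ")\n", sep = "")
  for (d in seq_along(object@demeNames))
    cat(sprintf("  %s: size %.4g, growth %.4g\n", object@demeNames[d],
                object@sizes[d], object@growth[d]))
  if (any(object@migration > 0)) {
    cat("  backward migration (row deme -> col deme, 4*N0*m):\n")
    m <- object@migration
    dimnames(m) <- list(object@demeNames, object@demeNames)
    print(signif(m, 4))
  }
  if (nrow(object@events)) {
    cat("  events:\n")
    print(object@events)
  }
})

#' Construct a LocusSimSpec
#'
#' @param locusId locus identifier.
#' @param fragmentLength fragment length L in bp.
#' @param muR relative substitution rate (across-locus mean 1).
#' @param rhoLocus locus-scaled recombination parameter 4*N0*r(L-1), before
#'   the ploidy adjustment.
#' @param ploidyFactor 1 autosomal, 0.75 Z-linked; multiplies both the locus
#'   theta and rho.
#' @return a [LocusSimSpec-class].
#' @export
LocusSimSpec <- function(locusId, fragmentLength, muR = 1, rhoLocus = 0,
                         ploidyFactor = 1) {
  new("LocusSimSpec", locusId = as.character(locusId),
      fragmentLength = as.integer(fragmentLength), muR = as.numeric(muR),
      rhoLocus = as.numeric(rhoLocus), ploidyFactor = as.numeric(ploidyFactor))
}

.eventCodes <- c(size_change = 1L, growth_change = 2L, split_join = 3L,
                 migration_change = 4L)

#' Simulate one locus under a demographic model
#'
#' Runs the structured-coalescent simulator (Hudson-style competing
#' exponentials over coalescence, migration and recombination, with
#' infinite-sites mutation at the locus-scaled theta).  The effective locus
#' theta is `thetaSite(model) * L * muR * ploidyFactor` and the effective
#' rho is `rhoLocus * ploidyFactor`.  Deterministic given the R random seed.
#'
#' @param model a [DemographicModel-class].
#' @param spec a [LocusSimSpec-class].
#' @param nPerDeme integer vector of sampled allele counts; unsampled demes
#'   (e.g. a hybridizing third population) get 0.  Recycled names are
#'   ignored; order follows `model@demeNames`.
#' @param returnMatrix keep the full 0/1 allele-by-site matrix (TRUE) or
#'   only per-deme derived-allele counts (faster, used by
#'   [posteriorPredictive()]).
#' @return a [SimulatedLocus-class].
#' @export
simulateLocus <- function(model, spec, nPerDeme, returnMatrix = TRUE) {
  stopifnot(is(model, "DemographicModel"), is(spec, "LocusSimSpec"))
  nd <- length(model@demeNames)
  if (length(nPerDeme) == 1L && nd > 1L)
    stop("nPerDeme must give a sample size for every deme")
  nPerDeme <- as.integer(rep_len(nPerDeme, nd))
  theta <- model@thetaSite * spec@fragmentLength * spec@muR *
    spec@ploidyFactor
  rho <- spec@rhoLocus * spec@ploidyFactor
  ev <- model@events
  res <- sim_locus_cpp(nPerDeme, model@sizes, model@growth, model@migration,
                       as.numeric(ev$time), .eventCodes[ev$kind],
                       as.integer(ev$deme), as.integer(ev$deme2),
                       as.numeric(ev$value), theta, rho, returnMatrix)
  demeOfRow <- factor(model@demeNames[res$sampleDeme + 1L],
                      levels = model@demeNames)
  mat <- if (returnMatrix) res$matrix else
    matrix(0L, 0L, length(res$positions))
  colnames(res$counts) <- model@demeNames
  new("SimulatedLocus", locusId = spec@locusId, matrix = mat,
      positions = res$positions, counts = res$counts, demes = demeOfRow,
      tmrca = res$tmrca, fragmentLength = spec@fragmentLength)
}

setMethod("show", "SimulatedLocus", function(object) {
  cat("SimulatedLocus '", object@locusId, "': S = ",
      length(object@positions), ", n = ",
      sum(table(object@demes)), " alleles, TMRCA = ",
      signif(object@tmrca, 4), " (4*N0 units)\n", sep = "")
})

#' Two-island model from a posterior draw
#'
#' Constant-size two-deme model with divergence infinitely far in the past.
#' The draw carries per-site-scaled, rate-corrected parameters:
#' `Theta_OW`, `Theta_NW` (4*N_e*mu per site) and `M_OW`, `M_NW` (m/mu,
#' immigration into the named population, forward in time).  Forward
#' immigration into deme i becomes, backward in time, movement of lineages
#' out of deme i, at rate 4*N0*m_i = Theta_OW * M_i in simulator units.
#'
#' @param draw named list or vector with `Theta_OW`, `Theta_NW`, `M_OW`,
#'   `M_NW`.
#' @return a [DemographicModel-class] anchored on the OW deme.
#' @export
buildTwoIsland <- function(draw) {
  draw <- as.list(draw)
  th <- c(draw$Theta_OW, draw$Theta_NW)
  if (any(th <= 0)) stop("Theta_OW and Theta_NW must be > 0")
  M <- c(draw$M_OW, draw$M_NW)
  if (any(M < 0)) stop("migration rates must be >= 0")
  if (all(M == 0))
    stop("both migration rates are 0: divergence is infinitely old, so ",
         "lineages can never coalesce across demes")
  mig <- matrix(0, 2, 2)
  mig[1, 2] <- draw$Theta_OW * draw$M_OW   # lineages in OW trace to NW
  mig[2, 1] <- draw$Theta_OW * draw$M_NW   # lineages in NW trace to OW
  DemographicModel(c("OW", "NW"),
                   sizes = c(1, draw$Theta_NW / draw$Theta_OW),
                   migration = mig, thetaSite = draw$Theta_OW,
                   modelType = "two_island")
}

#' Isolation-with-migration model from a posterior draw
#'
#' Two daughter demes founded at time t by fractions (1 - s) (OW) and s
#' (NW) of an ancestor of size theta_A, with exponential size change to the
#' present sizes and migration active between the split and the present.
#' The draw is in per-locus IM scale: `theta_OW`, `theta_NW`, `theta_A`
#' (4*N_e*u per locus), `M_OW`, `M_NW` (m/u, forward immigration into the
#' named population), `t` (= T*u) and `s` (founding fraction of the NW
#' population).  `geomeanL` is the geometric mean fragment length used to
#' express the anchor theta per site.
#'
#' @param draw named list or vector of IM parameters.
#' @param geomeanL geometric mean fragment length among loci.
#' @return a [DemographicModel-class] anchored on the present OW deme.
#' @export
buildIsolationMigration <- function(draw, geomeanL) {
  draw <- as.list(draw)
  with(draw, {
    if (any(c(theta_OW, theta_NW, theta_A) <= 0))
      stop("theta parameters must be > 0")
    if (s <= 0 || s >= 1) stop("founding fraction s must lie in (0, 1)")
    if (t <= 0) stop("divergence time t must be > 0")
    xNW <- theta_NW / theta_OW
    xA <- theta_A / theta_OW
    tMs <- t / theta_OW
    # size at the split equals the founding fraction of the ancestor
    alphaOW <- -log((1 - s) * xA) / tMs
    alphaNW <- -log(s * xA / xNW) / tMs
    mig <- matrix(0, 2, 2)
    mig[1, 2] <- theta_OW * M_OW
    mig[2, 1] <- theta_OW * M_NW
    ev <- rbind(.event(tMs, "split_join", 2L, 1L),
                .event(tMs, "size_change", 1L, value = xA))
    DemographicModel(c("OW", "NW"), sizes = c(1, xNW),
                     growth = c(alphaOW, alphaNW), migration = mig,
                     events = ev, thetaSite = theta_OW / geomeanL,
                     modelType = "isolation_migration")
  })
}

#' Pre-divergence bottleneck model
#'
#' Isolation-with-migration model in which the ancestral population keeps
#' shrinking (pastwards) at the OW growth rate between the split time t and
#' a bottleneck time tB, then instantaneously recovers to the long-term
#' size implied by the two-island (per-site) estimate of Theta_OW.
#'
#' @param imDraw IM draw as in [buildIsolationMigration()].
#' @param thetaOwLamarc per-site Theta_OW draw defining the pre-bottleneck
#'   (long-term ancestral) size.
#' @param geomeanL geometric mean fragment length among loci.
#' @param tB bottleneck time in IM units (same scale as `imDraw$t`); when
#'   NULL it is drawn uniformly between t and 2t.
#' @return a [DemographicModel-class].
#' @export
buildBottleneck <- function(imDraw, thetaOwLamarc, geomeanL, tB = NULL) {
  if (thetaOwLamarc <= 0) stop("thetaOwLamarc must be > 0")
  base <- buildIsolationMigration(imDraw, geomeanL)
  t <- as.list(imDraw)$t
  if (is.null(tB)) tB <- runif(1, t, 2 * t)
  if (tB < t || tB > 2 * t) stop("tB must lie in [t, 2t]")
  tMs <- t / as.list(imDraw)$theta_OW
  tBMs <- tB / as.list(imDraw)$theta_OW
  xRecover <- thetaOwLamarc / base@thetaSite
  alphaOW <- base@growth[1]
  ev <- rbind(base@events,
              .event(tMs, "growth_change", 1L, value = alphaOW),
              .event(tBMs, "size_change", 1L, value = xRecover))
  out <- DemographicModel(base@demeNames, base@sizes, base@growth,
                          base@migration, ev, base@thetaSite, "bottleneck")
  out
}

#' Hybridization model with a third (donor) population
#'
#' Isolation-with-migration model for the two focal populations plus a
#' third deme exchanging migrants with the OW deme only (any donor alleles
#' reaching NW must pass through OW, so donor-NW migration is structurally
#' zero).  The donor joins the focal ancestor at time `t_fd`.  Donor
#' parameters are scaled to theta_OW: `theta_fd_rel` = theta_fd/theta_OW,
#' `M_fd_to_OW` and `M_OW_to_fd` as effective migrant numbers
#' (theta_OW * M, i.e. already in 4*N0*m simulator units), and `t_fd_rel`
#' = t_fd/theta_OW (already in 4*N0 units).
#'
#' @param imDraw IM draw as in [buildIsolationMigration()].
#' @param fdDraw named list/vector with `theta_fd_rel`, `M_fd_to_OW`,
#'   `M_OW_to_fd`, `t_fd_rel`.
#' @param geomeanL geometric mean fragment length among loci.
#' @param migrationUntilJoin keep donor-OW migration active between the
#'   focal split and the donor join (default TRUE).
#' @return a three-deme [DemographicModel-class].
#' @export
buildHybridization <- function(imDraw, fdDraw, geomeanL,
                               migrationUntilJoin = TRUE) {
  base <- buildIsolationMigration(imDraw, geomeanL)
  fd <- as.list(fdDraw)
  tMs <- as.list(imDraw)$t / as.list(imDraw)$theta_OW
  if (fd$t_fd_rel <= tMs)
    stop("donor join time t_fd must postdate (be older than) the focal split")
  if (fd$theta_fd_rel <= 0) stop("theta_fd_rel must be > 0")
  mig <- matrix(0, 3, 3)
  mig[1:2, 1:2] <- base@migration
  # forward fd -> OW introgression: backward, OW lineages trace to fd
  mig[1, 3] <- fd$M_fd_to_OW
  mig[3, 1] <- fd$M_OW_to_fd
  ev <- base@events
  if (!migrationUntilJoin)
    ev <- rbind(ev,
                .event(tMs, "migration_change", 1L, 3L, 0),
                .event(tMs, "migration_change", 3L, 1L, 0))
  ev <- rbind(ev, .event(fd$t_fd_rel, "split_join", 3L, 1L))
  DemographicModel(c(base@demeNames, "FD"),
                   sizes = c(base@sizes, fd$theta_fd_rel),
                   growth = c(base@growth, 0), migration = mig,
                   events = ev, thetaSite = base@thetaSite,
                   modelType = "hybridization")
}

#' Realize nucleotide sequences from simulated segregating sites
#'
#' Draws a random ancestral sequence of length L, maps each segregating
#' site to a distinct integer column (ordered by its continuous position)
#' and substitutes a random alternative base for the derived state.
#'
#' @param simLocus a [SimulatedLocus-class] carrying the full 0/1 matrix.
#' @param L fragment length in bp (>= number of segregating sites).
#' @return a [LocusAlignment-class] with the simulated deme labels as
#'   population labels.
#' @export
realizeSequences <- function(simLocus, L = simLocus@fragmentLength) {
  stopifnot(is(simLocus, "SimulatedLocus"))
  S <- length(simLocus@positions)
  if (S > L) stop("more segregating sites (", S, ") than columns (", L, ")")
  if (nrow(simLocus@matrix) == 0L)
    stop("simLocus carries no allele matrix; rerun with returnMatrix = TRUE")
  n <- nrow(simLocus@matrix)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  cols <- if (S > 0) sort(sample.int(L, S)) else integer()
  seqs <- matrix(rep(anc, each = n), nrow = n)
  if (S > 0) {
    for (s in seq_len(S)) {
      derived <- sample(setdiff(bases, anc[cols[s]]), 1)
      seqs[simLocus@matrix[, s] == 1L, cols[s]] <- derived
    }
  }
  LocusAlignment(simLocus@locusId,
                 apply(seqs, 1, paste, collapse = ""),
                 as.character(simLocus@demes),
                 fragmentLength = L)
}

#' Summary statistics from simulated per-deme derived-allele counts
#'
#' Fast path used by the posterior predictive machinery: per-site
#' nucleotide diversity, Phi-ST, per-deme Tajima's D and their mean, and S,
#' computed directly from the segregating-site count matrix.  Exactly
#' equivalent to realizing sequences and calling [locusStats()] (a
#' cross-module identity exercised by the test-suite).
#'
#' @param simLocus a [SimulatedLocus-class].
#' @return one-row data.frame with columns `locus`, `pi`, `phi_st`, `tajd`
#'   (mean of per-deme values), `S`.
#' @export
simulatedLocusStats <- function(simLocus) {
  counts <- simLocus@counts
  nPer <- as.integer(table(simLocus@demes)[colnames(counts)])
  .statsFromCounts(counts, nPer, simLocus@fragmentLength, simLocus@locusId)
}

.statsFromCounts <- function(counts, nPer, L, locusId = "sim") {
  sampled <- nPer > 0
  counts <- counts[, sampled, drop = FALSE]
  nPer <- nPer[sampled]
  n <- sum(nPer)
  S <- nrow(counts)
  x <- if (S) rowSums(counts) else numeric()
  piTot <- if (S) sum(x * (n - x)) / .nPairs(n) else 0
  pi <- piTot / L
  # Tajima's D per sampled deme
  dPer <- vapply(seq_along(nPer), function(d) {
    nd <- nPer[d]
    if (nd < 4L) return(NA_real_)
    xd <- counts[, d]
    seg <- xd > 0L & xd < nd
    Sd <- sum(seg)
    if (Sd == 0L) return(NA_real_)
    piD <- sum(xd[seg] * (nd - xd[seg])) / .nPairs(nd)
    .tajimaD(Sd, piD, nd)
  }, numeric(1))
  tajd <- if (all(is.na(dPer))) NA_real_ else mean(dPer, na.rm = TRUE)
  # Phi-ST from pairwise-difference sums
  phi <- NA_real_
  if (S > 0 && length(nPer) >= 2L && all(nPer >= 2L)) {
    ssTotal <- sum(x * (n - x)) / 2 / n
    ssWithin <- sum(vapply(seq_along(nPer), function(d) {
      xd <- counts[, d]
      sum(xd * (nPer[d] - xd)) / 2 / nPer[d]
    }, numeric(1)))
    P <- length(nPer)
    sigmaW <- ssWithin / (n - P)
    nprime <- (n - sum(nPer^2) / n) / (P - 1)
    sigmaA <- ((ssTotal - ssWithin) / (P - 1) - sigmaW) / nprime
    phi <- if (sigmaA + sigmaW == 0) NA_real_ else sigmaA / (sigmaA + sigmaW)
  }
  data.frame(locus = locusId, pi = pi, phi_st = phi, tajd = tajd, S = S,
             stringsAsFactors = FALSE)
}

#' Write simulated loci in the ms output dialect
#'
#' Emits the classic text format: a command line, a seed line, then for
#' each replicate a `//` separator, `segsites: k`, a `positions:` line and
#' the 0/1 haplotype rows.
#'
#' @param sims a [SimulatedLocus-class] or list of them.
#' @param path output file.
#' @param cmdline first header line.
#' @param seeds seeds to print on the second line.
#' @return `path`, invisibly.
#' @export
writeMs <- function(sims, path, cmdline = NULL, seeds = c(0L, 0L, 0L)) {
  if (is(sims, "SimulatedLocus")) sims <- list(sims)
  n <- nrow(sims[[1]]@matrix)
  if (is.null(cmdline)) cmdline <- paste("coalfit", n, length(sims))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(cmdline, paste(seeds, collapse = " ")), con)
  for (sim in sims) {
    writeLines(c("", "//"), con)
    S <- length(sim@positions)
    writeLines(paste0("segsites: ", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", sim@positions), collapse = " ")),
                 con)
      writeLines(apply(sim@matrix, 1, paste, collapse = ""), con)
    }
  }
  invisible(path)
}

#' Read an ms-format file
#'
#' @param path path to a file in the ms output dialect.
#' @return list of lists with elements `positions` (numeric) and `matrix`
#'   (0/1 integer matrix, alleles x sites).
#' @export
readMs <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  if (!length(starts)) stop("no replicates ('//' records) found in ", path)
  lapply(starts, function(st) {
    segLine <- lines[st + 1L]
    S <- as.integer(sub("segsites:\\s*", "", segLine))
    if (S == 0L)
      return(list(positions = numeric(),
                  matrix = matrix(0L, 0L, 0L)))
    pos <- as.numeric(strsplit(sub("positions:\\s*", "", lines[st + 2L]),
                               "\\s+")[[1]])
    rows <- character()
    i <- st + 3L
    while (i <= length(lines) && grepl("^[01]+$", lines[i])) {
      rows <- c(rows, lines[i])
      i <- i + 1L
    }
    mat <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    list(positions = pos, matrix = mat)
  })
}
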