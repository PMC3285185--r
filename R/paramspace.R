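.posteriorSchemas <- list(
  lamarc = c("Theta_OW", "Theta_NW", "M_OW", "M_NW", "r"),
  im = c("theta_OW", "theta_NW", "theta_A", "M_OW", "M_NW", "t", "s"),
  fd = c("theta_fd_rel", "M_fd_to_OW", "M_OW_to_fd", "t_fd_rel")
)

.posteriorScaling <- c(lamarc = "per_site", im = "per_locus",
                       rates = "relative", recomb = "relative",
                       fd = "relative")

#' Read and validate a posterior-sample table
#'
#' Tab-separated with header.  Dialects: `lamarc` (columns `Theta_OW`,
#' `Theta_NW`, `M_OW`, `M_NW`, `r`; per-site scaling), `im` (`theta_OW`,
#' `theta_NW`, `theta_A`, `M_OW`, `M_NW`, `t`, `s`; per-locus scaling),
#' `rates` (one column per locus; every row must average 1), `recomb` (one
#' column per locus), `fd` (donor-population draws scaled to theta_OW).
#'
#' @param path TSV path.
#' @param source one of `"lamarc"`, `"im"`, `"rates"`, `"recomb"`, `"fd"`.
#' @return a [PosteriorTable-class].
#' @export
readPosterior <- function(path, source) {
  source <- match.arg(source, names(.posteriorScaling))
  if (file.size(path) == 0) stop("empty posterior file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("posterior table has no rows: ", path)
  need <- .posteriorSchemas[[source]]
  if (!is.null(need)) {
    missing <- setdiff(need, names(tab))
    if (length(missing))
      stop(source, " table is missing columns: ",
           paste(missing, collapse = ", "))
    tab <- tab[need]
  }
  for (col in names(tab)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad))
      stop("non-numeric or non-finite value at row ", bad[1], ", column '",
           col, "'")
    tab[[col]] <- as.numeric(tab[[col]])
  }
  PosteriorTable(source, tab)
}

#' @rdname readPosterior
#' @param tab data.frame of draws (already numeric).
#' @export
PosteriorTable <- function(source, tab) {
  new("PosteriorTable", source = source, table = tab,
      scaling = unname(.posteriorScaling[source]))
}

setMethod("show", "PosteriorTable", function(object) {
  cat("PosteriorTable [", object@source, ", ", object@scaling, "]: ",
      nrow(object@table), " draws x ", ncol(object@table), " columns\n",
      sep = "")
})

#' Rate-correct a per-site (LAMARC-style) posterior draw
#'
#' Locus-specific per-site estimates are placed on the across-locus mean
#' rate scale by dividing Theta by a relative substitution-rate draw and
#' multiplying M by the same draw; Z-linked loci are additionally scaled by
#' the ploidy factor.  This propagates substitution-rate uncertainty into
#' the demographic draws.
#'
#' @param draw named list/vector with `Theta_OW`, `Theta_NW`, `M_OW`,
#'   `M_NW` (and optionally `r`, passed through).
#' @param muRDraw relative substitution-rate draw for this locus.
#' @param ploidy ploidy factor (0.75 for Z-linked loci).
#' @return named list of corrected parameters.
#' @export
rescaleLamarcDraw <- function(draw, muRDraw, ploidy = 1) {
  draw <- as.list(draw)
  vals <- unlist(draw[c("Theta_OW", "Theta_NW", "M_OW", "M_NW")])
  if (any(vals <= 0) || muRDraw <= 0 || ploidy <= 0)
    stop("all inputs to rescaleLamarcDraw must be positive")
  out <- draw
  out$Theta_OW <- ploidy * draw$Theta_OW / muRDraw
  out$Theta_NW <- ploidy * draw$Theta_NW / muRDraw
  out$M_OW <- draw$M_OW * muRDraw
  out$M_NW <- draw$M_NW * muRDraw
  out
}

#' Per-locus simulator theta from a per-locus (IM-style) draw
#'
#' theta_locus_i = (theta / geomean(L)) * L_i * muR_i * ploidy_i.
#'
#' @param theta per-locus-scaled theta draw.
#' @param fragmentLengths vector of locus lengths.
#' @param muR vector of relative substitution rates, same length.
#' @param ploidy vector of ploidy factors (default 1).
#' @return numeric vector of per-locus theta values.
#' @export
rescaleImDraw <- function(theta, fragmentLengths, muR,
                          ploidy = rep(1, length(fragmentLengths))) {
  if (any(fragmentLengths <= 0)) stop("fragment lengths must be > 0")
  if (length(muR) != length(fragmentLengths) ||
      length(ploidy) != length(fragmentLengths))
    stop("fragmentLengths, muR and ploidy must have equal lengths")
  theta / .geomean(fragmentLengths) * fragmentLengths * muR * ploidy
}

.geomean <- function(x) exp(mean(log(x)))

#' Assemble joint simulation histories from posterior tables
#'
#' Draws `n` joint parameter vectors: demographic rows are sampled without
#' replacement (preserving within-row correlations), relative
#' substitution-rate rows are kept intact (preserving the mean-1
#' constraint) and paired with histories by a random permutation, and
#' recombination rates are sampled independently per locus.  Locus-scaled
#' recombination is formed as rho_l = r * theta_site_l * (L_l - 1) with
#' theta_site_l the locus's own per-site theta (including muR).
#'
#' @param demography a [PosteriorTable-class] of source `lamarc` or `im`.
#' @param rates a `rates` [PosteriorTable-class] with one column per locus.
#' @param recomb a `recomb` [PosteriorTable-class] with one column per
#'   locus, or NULL for no recombination.
#' @param loci data.frame with columns `locus`, `length`, `ploidy`.
#' @param n number of histories.
#' @param model one of `"two_island"`, `"isolation_migration"`,
#'   `"bottleneck"`, `"hybridization"`; defaults to match the demography
#'   source.
#' @param lamarcTheta numeric vector (or lamarc [PosteriorTable-class]) of
#'   per-site Theta_OW draws; required for the bottleneck model.
#' @param fd an `fd` [PosteriorTable-class]; required for hybridization.
#' @param replace sample demographic rows with replacement when the table
#'   has fewer than `n` rows.
#' @param seed integer seed recorded in the HistorySet (set before
#'   sampling).
#' @return a [HistorySet-class].
#' @export
assembleHistories <- function(demography, rates, recomb, loci, n = 1000,
                              model = NULL, lamarcTheta = NULL, fd = NULL,
                              replace = FALSE, seed = 1L) {
  stopifnot(is(demography, "PosteriorTable"), is(rates, "PosteriorTable"))
  if (is.null(model))
    model <- switch(demography@source, lamarc = "two_island",
                    im = "isolation_migration",
                    stop("cannot infer model from source ",
                         demography@source))
  if (model != "two_island" && demography@source != "im")
    stop(model, " histories require an im demography table")
  L <- nrow(loci)
  if (!all(loci$locus %in% names(rates@table)))
    stop("rates table lacks columns for loci: ",
         paste(setdiff(loci$locus, names(rates@table)), collapse = ", "))
  set.seed(seed)
  pick <- function(tab, what) {
    m <- nrow(tab)
    if (m < n && !replace)
      stop(what, " table has ", m, " rows but ", n,
           " histories requested (set replace = TRUE to resample)")
    sample.int(m, n, replace = m < n || replace)
  }
  demRows <- pick(demography@table, "demography")
  draws <- demography@table[demRows, , drop = FALSE]
  rownames(draws) <- NULL
  rateRows <- pick(rates@table, "rates")[sample.int(n)]  # permuted assignment
  muR <- as.matrix(rates@table[rateRows, loci$locus, drop = FALSE])
  rownames(muR) <- NULL
  if (!is.null(recomb)) {
    if (!all(loci$locus %in% names(recomb@table)))
      stop("recomb table lacks columns for loci: ",
           paste(setdiff(loci$locus, names(recomb@table)), collapse = ", "))
    rho <- matrix(vapply(loci$locus, function(l) {
      recomb@table[[l]][pick(recomb@table, "recomb")]
    }, numeric(n)), nrow = n)
  } else {
    rho <- matrix(0, n, L)
  }
  colnames(rho) <- loci$locus
  extras <- list()
  if (model == "bottleneck") {
    if (is.null(lamarcTheta))
      stop("bottleneck histories need lamarcTheta (per-site Theta_OW draws)")
    if (is(lamarcTheta, "PosteriorTable"))
      lamarcTheta <- lamarcTheta@table$Theta_OW
    extras$tB <- runif(n, draws$t, 2 * draws$t)
    idx <- if (length(lamarcTheta) >= n)
      sample.int(length(lamarcTheta), n) else
      sample.int(length(lamarcTheta), n, replace = TRUE)
    extras$thetaOwLamarc <- lamarcTheta[idx]
  }
  if (model == "hybridization") {
    if (is.null(fd)) stop("hybridization histories need an fd table")
    fdRows <- pick(fd@table, "fd")
    extras$fd <- fd@table[fdRows, , drop = FALSE]
    rownames(extras$fd) <- NULL
  }
  new("HistorySet", modelType = model, draws = draws, muR = muR, rho = rho,
      loci = as.data.frame(loci), extras = extras,
      geomeanL = .geomean(loci$length), seed = as.numeric(seed),
      provenance = list(demRows = demRows, rateRows = rateRows))
}

#' @rdname HistorySet-class
#' @export
setMethod("nHistories", "HistorySet", function(x) nrow(x@draws))

#' @rdname HistorySet-class
#' @export
setMethod("modelType", "HistorySet", function(x) x@modelType)

setMethod("show", "HistorySet", function(object) {
  cat("HistorySet [", object@modelType, "]: ", nrow(object@draws),
      " histories x ", nrow(object@loci), " loci (seed ", object@seed,
      ")\n", sep = "")
})

#' Demographic model for one assembled history
#'
#' @param histories a [HistorySet-class].
#' @param h history index.
#' @return a [DemographicModel-class].
#' @export
historyModel <- function(histories, h) {
  draw <- as.list(histories@draws[h, ])
  switch(histories@modelType,
    two_island = buildTwoIsland(draw),
    isolation_migration = buildIsolationMigration(draw, histories@geomeanL),
    bottleneck = buildBottleneck(draw, histories@extras$thetaOwLamarc[h],
                                 histories@geomeanL,
                                 tB = histories@extras$tB[h]),
    hybridization = buildHybridization(draw,
                                       as.list(histories@extras$fd[h, ]),
                                       histories@geomeanL))
}

#' Per-locus simulation specs for one history
#'
#' @param histories a [HistorySet-class].
#' @param h history index.
#' @param thetaSite the anchor per-site theta of the history's model (used
#'   for the locus-scaled recombination parameter).
#' @return list of [LocusSimSpec-class] objects.
#' @export
historyLocusSpecs <- function(histories, h, thetaSite) {
  loci <- histories@loci
  lapply(seq_len(nrow(loci)), function(l) {
    LocusSimSpec(loci$locus[l], loci$length[l],
                 muR = histories@muR[h, l],
                 rhoLocus = histories@rho[h, l] * thetaSite *
                   histories@muR[h, l] * (loci$length[l] - 1),
                 ploidyFactor = loci$ploidy[l])
  })
}

#' Joint estimate across loci by biweight-kernel density product
#'
#' Smooths each locus's posterior sample with a biweight (quartic) kernel
#' on a common grid, multiplies the densities across loci in log space,
#' normalises, and reports the mode and the narrowest interval containing
#' the requested mass (grid-based highest-density interval).
#'
#' @param samples list of numeric vectors (posterior draws per locus).
#' @param gridSize number of grid points (default 512).
#' @param conf interval mass (default 0.95).
#' @param bwScale multiplier on Silverman's rule-of-thumb bandwidth.
#' @return list with `grid`, `density`, `mode`, `interval` (length 2),
#'   `perLocus` (matrix of smoothed densities).
#' @export
jointEstimate <- function(samples, gridSize = 512, conf = 0.95,
                          bwScale = 0.9) {
  if (!length(samples)) stop("need at least one locus sample")
  pooled <- unlist(samples)
  lim <- quantile(pooled, c(0.001, 0.999), names = FALSE)
  if (lim[1] == lim[2]) lim <- lim + c(-1, 1) * max(1e-8, abs(lim[1]) * 1e-6)
  grid <- seq(lim[1], lim[2], length.out = gridSize)
  dens <- vapply(samples, function(x) {
    bw <- bwScale * stats::bw.nrd0(x)
    if (!is.finite(bw) || bw <= 0) bw <- max(1e-8, diff(lim) / gridSize)
    d <- stats::density(x, bw = bw, kernel = "biweight",
                        from = lim[1], to = lim[2], n = gridSize)
    y <- d$y
    y[y < 1e-12 * max(y)] <- 0   # suppress FFT smoothing ripple
    y
  }, numeric(gridSize))
  logProd <- rowSums(log(pmax(dens, 0)))
  if (!any(is.finite(logProd)))
    stop("locus posteriors have disjoint supports: joint density is zero ",
         "everywhere")
  logProd <- logProd - max(logProd[is.finite(logProd)])
  joint <- exp(logProd)
  joint[!is.finite(joint)] <- 0
  step <- grid[2] - grid[1]
  joint <- joint / (sum(joint) * step)
  ord <- order(joint, decreasing = TRUE)
  mass <- cumsum(joint[ord]) * step
  inHpd <- ord[seq_len(which(mass >= conf)[1])]
  list(grid = grid, density = joint, mode = grid[which.max(joint)],
       interval = range(grid[inHpd]), perLocus = dens)
}

#' @rdname HistorySet-class
#' @param i history indices
#' @param j,drop,... ignored
#' @export
setMethod("[", "HistorySet", function(x, i, j, ..., drop = FALSE) {
  ex <- x@extras
  if (!is.null(ex$tB)) ex$tB <- ex$tB[i]
  if (!is.null(ex$thetaOwLamarc)) ex$thetaOwLamarc <- ex$thetaOwLamarc[i]
  if (!is.null(ex$fd)) ex$fd <- ex$fd[i, , drop = FALSE]
  new("HistorySet", modelType = x@modelType,
      draws = x@draws[i, , drop = FALSE],
      muR = x@muR[i, , drop = FALSE], rho = x@rho[i, , drop = FALSE],
      loci = x@loci, extras = ex, geomeanL = x@geomeanL, seed = x@seed,
      provenance = list(parent = x@provenance, subset = i))
})
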