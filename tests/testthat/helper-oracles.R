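# Independent oracles used to check the package implementations.  These are
# deliberately naive (brute force over pairs, direct textbook formulas) and
# share no code with the implementation paths they verify.

# O(n^2 L) brute-force nucleotide diversity with complete gap deletion
oraclePi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(m, 2, function(col) !any(col %in% c("-", "N")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(m[i, ] != m[j, ])
  list(pi = tot / choose(n, 2) / ncol(m), nSites = ncol(m),
       meanDiffs = tot / choose(n, 2))
}

# Tajima (1989) evaluated directly from S and mean pairwise differences
oracleTajimaD <- function(S, meanDiffs, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (meanDiffs - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# direct AMOVA arithmetic on a matrix of pairwise differences
oraclePhiSt <- function(seqs, labels) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(m, 2, function(col) !any(col %in% c("-", "N")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  ssTotal <- sum(d[upper.tri(d)]) / n
  groups <- split(seq_len(n), labels)
  ssWithin <- sum(vapply(groups, function(g) {
    dg <- d[g, g, drop = FALSE]
    sum(dg[upper.tri(dg)]) / length(g)
  }, numeric(1)))
  P <- length(groups)
  msAmong <- (ssTotal - ssWithin) / (P - 1)
  sigmaW <- ssWithin / (n - P)
  nprime <- (n - sum(lengths(groups)^2) / n) / (P - 1)
  sigmaA <- (msAmong - sigmaW) / nprime
  sigmaA / (sigmaA + sigmaW)
}

# exhaustive Benjamini-Hochberg step-up: largest k with p_(k) <= q k / m
oracleBH <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= q * i / m) k <- i
  decisions <- logical(m)
  if (k > 0) decisions[ord[seq_len(k)]] <- TRUE
  decisions
}

# discrete-generation Wright-Fisher ancestry oracle for a pair of lineages
# in a symmetric two-deme model: K gene copies per deme, per-generation
# per-lineage migration probability mig; returns coalescence times in
# generations.  Each generation a lineage first picks its parental deme
# (migrates with probability mig), then the pair coalesces with
# probability 1/K if both parents are in the same deme.
wfPairTimes <- function(K, mig, reps, sameDeme, maxGen = 1e6) {
  d1 <- integer(reps)
  d2 <- if (sameDeme) integer(reps) else rep(1L, reps)
  tt <- integer(reps)
  alive <- rep(TRUE, reps)
  gen <- 0L
  while (any(alive)) {
    gen <- gen + 1L
    if (gen > maxGen) stop("WF oracle exceeded generation budget")
    idx <- which(alive)
    k <- length(idx)
    d1[idx] <- (d1[idx] + (runif(k) < mig)) %% 2L
    d2[idx] <- (d2[idx] + (runif(k) < mig)) %% 2L
    co <- d1[idx] == d2[idx] & runif(k) < 1 / K
    tt[idx[co]] <- gen
    alive[idx[co]] <- FALSE
  }
  tt
}

# quick panmictic constant-size alignment-free simulation summary
simPanmicticStats <- function(thetaLocus, n, reps, L = 300L, seed = 1) {
  dem <- DemographicModel("pop", sizes = 1, thetaSite = thetaLocus / L,
                          modelType = "panmictic")
  spec <- LocusSimSpec("x", L)
  out <- matrix(NA_real_, reps, 4)
  for (i in seq_len(reps)) {
    set.seed(deriveSeed(seed, i))
    sim <- simulateLocus(dem, spec, n, returnMatrix = FALSE)
    st <- simulatedLocusStats(sim)
    out[i, ] <- c(st$pi * L, st$S, st$tajd, sim@tmrca)
  }
  colnames(out) <- c("piLocus", "S", "tajd", "tmrca")
  as.data.frame(out)
}

toyAlignment <- function() {
  LocusAlignment("toy", c("AAA", "AAT", "ATT", "TTT"),
                 c("popA", "popA", "popB", "popB"))
}
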