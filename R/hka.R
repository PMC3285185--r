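#' Read an HKA input table
#'
#' Tab-separated with header columns `locus`, `n_within`, `L`, `S_within`,
#' `D_out`, `outgroup`.
#'
#' @param path TSV path.
#' @return data.frame suitable for [hkaTest()].
#' @export
readHKAInput <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "n_within", "L", "S_within", "D_out", "outgroup")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("HKA table is missing columns: ", paste(missing, collapse = ", "))
  tab
}

.hkaA <- function(n) vapply(n, function(k) sum(1 / seq_len(k - 1)), numeric(1))
.hkaB <- function(n) vapply(n, function(k) sum(1 / seq_len(k - 1)^2),
                            numeric(1))

#' Multilocus HKA test of selective neutrality
#'
#' Hudson-Kreitman-Aguade (1987) goodness-of-fit test comparing
#' within-species polymorphism (segregating sites S_i) with divergence to
#' an outgroup (mean pairwise differences D_i) across loci.  Under
#' neutrality both are proportional to the same locus mutation parameter:
#' E(S_i) = theta_i * a(n_i) and E(D_i) = theta_i * (T + 1), where T is the
#' species divergence time in units of 2N generations and the "+1" term is
#' the expected coalescent time of the two lineages in the ancestor
#' (assumed the same size as the focal species).  Variances follow the
#' original moment formulas: Var(S_i) = theta_i*a + theta_i^2*b,
#' Var(D_i) = E(D_i) + theta_i^2.  The locus thetas and T are fitted by the
#' moment equations (one-dimensional root solve in T), and the statistic
#' X2 = sum over polymorphism and divergence cells of (obs-exp)^2/var is
#' referred to a chi-square with L - 1 degrees of freedom.
#'
#' @param input data.frame with columns `locus`, `n_within`, `L`,
#'   `S_within`, `D_out` (one outgroup at a time).
#' @return an [HKAResult-class].
#' @export
hkaTest <- function(input) {
  need <- c("locus", "n_within", "S_within", "D_out")
  missing <- setdiff(need, names(input))
  if (length(missing))
    stop("HKA input is missing columns: ", paste(missing, collapse = ", "))
  L <- nrow(input)
  if (L < 2L) stop("HKA test needs at least 2 loci")
  if (any(input$S_within < 0) || any(input$D_out < 0))
    stop("S_within and D_out must be non-negative")
  S <- as.numeric(input$S_within)
  D <- as.numeric(input$D_out)
  nw <- as.integer(input$n_within)
  if (any(nw < 2L)) stop("n_within must be >= 2 for every locus")
  if (sum(S) + sum(D) == 0) stop("all-zero data: nothing to fit")
  if (sum(S) == 0 || sum(D) == 0)
    stop("HKA moment equations require both polymorphism and divergence ",
         "totals to be positive")
  a <- .hkaA(nw)

  thetaOf <- function(Tdiv) (S + D) / (a + Tdiv + 1)
  gap <- function(Tdiv) sum(thetaOf(Tdiv) * a) - sum(S)
  # gap is decreasing in T; bracket the root
  lo <- -1 + 1e-9
  hi <- 1
  while (gap(hi) > 0 && hi < 1e12) hi <- hi * 10
  if (gap(hi) > 0) stop("HKA moment equations failed to converge: ",
                        "no divergence signal (gap > 0 at T = 1e12)")
  if (gap(lo) < 0) stop("HKA moment equations failed to converge: ",
                        "no polymorphism signal")
  Tdiv <- uniroot(gap, c(lo, hi), tol = 1e-10)$root
  theta <- thetaOf(Tdiv)

  eS <- theta * a
  vS <- theta * a + theta^2 * .hkaB(nw)
  eD <- theta * (Tdiv + 1)
  vD <- eD + theta^2
  contrib <- (S - eS)^2 / vS + (D - eD)^2 / vD
  names(contrib) <- as.character(input$locus)
  X2 <- sum(contrib)
  df <- L - 1L
  cells <- data.frame(locus = input$locus,
                      S_obs = S, S_exp = eS, S_var = vS,
                      D_obs = D, D_exp = eD, D_var = vD,
                      stringsAsFactors = FALSE)
  new("HKAResult", theta = setNames(theta, input$locus), Tdiv = Tdiv,
      cells = cells, contributions = contrib, X2 = X2, df = df,
      pValue = pchisq(X2, df, lower.tail = FALSE))
}

setMethod("show", "HKAResult", function(object) {
  cat(sprintf(
    "HKA test: %d loci, X2 (sum of deviations) = %.3f, df = %d, p = %.4g\n",
    length(object@theta), object@X2, object@df, object@pValue))
  cat(sprintf("  fitted divergence T = %.4g (2N generations)\n",
              object@Tdiv))
  top <- sort(object@contributions, decreasing = TRUE)[1:min(3, length(object@contributions))]
  cat("  largest deviations:",
      paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
})

#' Iterative removal of HKA outlier loci
#'
#' While the HKA test is significant at `alpha`, removes the locus with
#' the highest overall deviation (its summed polymorphism + divergence
#' contribution; ties broken by input order with a warning) and repeats,
#' until the test is no longer significant.
#'
#' @param input data.frame as for [hkaTest()].
#' @param alpha significance level for each round.
#' @return list with `removed` (character vector in removal order),
#'   `finalP`, `rounds` (data.frame of per-round X2/df/p and removed
#'   locus).
#' @export
iterativeRemoval <- function(input, alpha = 0.05) {
  removed <- character()
  rounds <- list()
  cur <- input
  repeat {
    res <- hkaTest(cur)
    pick <- NA_character_
    if (res@pValue <= alpha) {
      if (nrow(cur) <= 2L)
        stop("test still significant with only 2 loci remaining; ",
             "cannot remove further loci")
      contrib <- res@contributions
      top <- which(contrib == max(contrib))
      if (length(top) > 1L)
        warning("tie in highest deviation; removing the first in input ",
                "order (", names(contrib)[top[1]], ")")
      pick <- names(contrib)[top[1]]
    }
    rounds[[length(rounds) + 1L]] <- data.frame(
      n_loci = nrow(cur), X2 = res@X2, df = res@df, p = res@pValue,
      removed = pick, stringsAsFactors = FALSE)
    if (is.na(pick)) break
    removed <- c(removed, pick)
    cur <- cur[as.character(cur$locus) != pick, , drop = FALSE]
  }
  list(removed = removed, finalP = rounds[[length(rounds)]]$p,
       rounds = do.call(rbind, rounds))
}

#' Consensus outliers across outgroup comparisons
#'
#' Loci removed in strictly more than `threshold` of the removal lists
#' (one list per outgroup comparison) are declared significant outliers.
#'
#' @param removalLists list of character vectors (removal orders).
#' @param threshold consensus fraction (default 0.5).
#' @return character vector of consensus outlier loci.
#' @export
consensusOutliers <- function(removalLists, threshold = 0.5) {
  if (!length(removalLists)) return(character())
  all <- unlist(removalLists)
  if (!length(all)) return(character())
  counts <- table(all)
  names(counts)[counts / length(removalLists) > threshold]
}
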