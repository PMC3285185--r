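#' Construct a LocusAlignment
#'
#' @param locusId single character locus identifier.
#' @param sequences a [Biostrings::DNAStringSet], or a character vector of
#'   equal-length sequences over A, C, G, T, `-`, N.
#' @param popLabels character or factor of population labels, one per
#'   sequence.
#' @param fragmentLength reference fragment length in bp; defaults to the
#'   alignment width.
#' @param ploidyFactor 1 for autosomal loci, 0.75 for Z-linked loci.
#'
#' @return a [LocusAlignment-class] object.
#' @examples
#' aln <- LocusAlignment("toy", c("AAA", "AAT", "ATT", "TTT"),
#'                       c("popA", "popA", "popB", "popB"))
#' nucleotideDiversity(aln)
#' @export
LocusAlignment <- function(locusId, sequences, popLabels,
                           fragmentLength = NULL, ploidyFactor = 1) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(fragmentLength)) {
    w <- Biostrings::width(sequences)
    fragmentLength <- if (length(w)) w[1] else 0L
  }
  new("LocusAlignment",
      locusId = as.character(locusId),
      sequences = sequences,
      popLabels = as.factor(popLabels),
      fragmentLength = as.integer(fragmentLength),
      ploidyFactor = as.numeric(ploidyFactor))
}

#' @rdname LocusAlignment-class
#' @aliases locusId,LocusAlignment-method
#' @export
setMethod("locusId", "LocusAlignment", function(x) x@locusId)

#' @rdname LocusAlignment-class
#' @export
setMethod("popLabels", "LocusAlignment", function(x) x@popLabels)

#' @rdname LocusAlignment-class
#' @export
setMethod("fragmentLength", "LocusAlignment", function(x) x@fragmentLength)

#' @rdname LocusAlignment-class
#' @export
setMethod("ploidyFactor", "LocusAlignment", function(x) x@ploidyFactor)

#' @rdname LocusAlignment-class
#' @export
setMethod("length", "LocusAlignment", function(x) length(x@sequences))

setMethod("show", "LocusAlignment", function(object) {
  cat("LocusAlignment '", object@locusId, "': ",
      length(object@sequences), " alleles x ",
      if (length(object@sequences)) Biostrings::width(object@sequences)[1] else 0,
      " bp\n", sep = "")
  tab <- table(object@popLabels)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("  fragmentLength:", object@fragmentLength,
      " ploidyFactor:", object@ploidyFactor, "\n")
})

#' Read one locus from a FASTA file with a sample-to-population map
#'
#' @param path path to a FASTA file of phased alleles for one locus.
#' @param popMap either a named character vector mapping record ids to
#'   population labels, a two-column data.frame (sample, population), or the
#'   path of a two-column tab-separated file without header comment lines.
#' @param locusId locus identifier; defaults to the file name without
#'   extension.
#' @param fragmentLength,ploidyFactor see [LocusAlignment()].
#'
#' @return a [LocusAlignment-class].
#' @export
loadLocusFasta <- function(path, popMap, locusId = NULL,
                           fragmentLength = NULL, ploidyFactor = 1) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L)
    stop("ragged alignment in ", path, ": sequence lengths ",
         paste(unique(w), collapse = ", "))
  map <- .asPopMap(popMap)
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(ids, names(map))
  if (length(missing))
    stop("records missing from population map: ",
         paste(missing, collapse = ", "))
  if (is.null(locusId)) locusId <- sub("\\.[^.]*$", "", basename(path))
  LocusAlignment(locusId, seqs, map[ids],
                 fragmentLength = fragmentLength,
                 ploidyFactor = ploidyFactor)
}

.asPopMap <- function(popMap) {
  if (is.character(popMap) && length(popMap) == 1L && file.exists(popMap)) {
    tab <- utils::read.delim(popMap, header = FALSE,
                             col.names = c("sample", "population"),
                             comment.char = "#",
                             stringsAsFactors = FALSE)
    popMap <- tab
  }
  if (is.data.frame(popMap)) {
    out <- as.character(popMap[[2]])
    names(out) <- as.character(popMap[[1]])
    return(out)
  }
  if (is.null(names(popMap)) || any(names(popMap) == ""))
    stop("popMap must be named by sample id")
  popMap
}

#' Write a LocusAlignment back to FASTA
#'
#' Sequences are written byte-exact (gaps and Ns preserved), so a
#' write/read round trip reproduces the alignment.
#'
#' @param aln a [LocusAlignment-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeLocusFasta <- function(aln, path) {
  seqs <- aln@sequences
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("%s_allele%03d", aln@locusId, seq_along(seqs))
  Biostrings::writeXStringSet(seqs, path, width = 20000L)
  invisible(path)
}
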