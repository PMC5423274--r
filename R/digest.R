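#' Coerce input to a named DNAStringSet
#'
#' @param genome A `Biostrings::DNAStringSet`, a named character vector of
#'   chromosome sequences, or a single unnamed sequence (named `"chr1"`).
#' @return A named `DNAStringSet`.
#' @keywords internal
#' @export
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- genome
  } else if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(toupper(genome))
  } else if (methods::is(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
  } else {
    stop("genome must be a DNAStringSet or a character vector of sequences")
  }
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    names(g) <- paste0("chr", seq_along(g))
  }
  g
}

#' Find restriction cut positions in a sequence
#'
#' Scans the top strand for every occurrence of the enzyme's recognition
#' sequence, expanding IUPAC degenerate codes and honouring overlapping
#' matches. The cut position is reported in 0-based between-base coordinates:
#' a cut at position `k` falls between bases `k` and `k + 1` of the 1-based
#' sequence, i.e. at match start (0-based) plus `cut_offset`.
#'
#' @param sequence A single chromosome: `DNAString`, or character string over
#'   A/C/G/T.
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of unique 0-based cut positions.
#' @examples
#' toyE <- restriction_enzyme("toyE", "GAATTC", 1)
#' find_sites("TTGAATTCAA", toyE)  # 3
#' @export
find_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (is.character(sequence)) sequence <- Biostrings::DNAString(toupper(sequence))
  if (length(sequence) < nchar(enzyme$recognition)) return(integer(0))
  m <- Biostrings::matchPattern(enzyme$recognition, sequence, fixed = FALSE)
  cuts <- Biostrings::start(m) - 1L + enzyme$cut_offset
  sort(unique(as.integer(cuts)))
}

#' Digest genome sequences with one or more restriction enzymes
#'
#' Cut positions from all enzymes are merged per chromosome and the
#' fragments are the intervals between consecutive cuts plus the two
#' chromosome-end intervals. Fragment coordinates are 0-based half-open
#' (BED convention); concatenating the fragment sequences of a chromosome in
#' order reconstructs it exactly. Each internal boundary is labelled with the
#' enzyme that cut it; chromosome ends are labelled `"CHROM_END"`. When two
#' enzymes cut at the same position the label of the first enzyme in
#' `enzymes` is kept.
#'
#' @param genome See [as_genome()].
#' @param enzymes A [restriction_enzyme()] or list of them.
#' @return A data frame with columns `chrom`, `start`, `end`, `left_enzyme`,
#'   `right_enzyme`, `length`, `gc_fraction`.
#' @examples
#' toyE <- restriction_enzyme("toyE", "GAATTC", 1)
#' digest(c(chr1 = "TTGAATTCAA"), toyE)
#' @export
digest <- function(genome, enzymes) {
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  stopifnot(length(enzymes) >= 1L,
            all(vapply(enzymes, inherits, logical(1), "restriction_enzyme")))
  genome <- as_genome(genome)

  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chrom_seq <- genome[[ci]]
    len <- length(chrom_seq)
    if (len == 0L) next
    cuts <- integer(0)
    labels <- character(0)
    for (enz in enzymes) {
      cz <- find_sites(chrom_seq, enz)
      cz <- cz[cz > 0L & cz < len]  # cuts at the very ends are no-ops
      new <- !(cz %in% cuts)
      cuts <- c(cuts, cz[new])
      labels <- c(labels, rep(enz$name, sum(new)))
    }
    ord <- order(cuts)
    cuts <- cuts[ord]
    labels <- labels[ord]
    starts <- c(0L, cuts)
    ends <- c(cuts, len)
    vw <- Biostrings::Views(chrom_seq, start = starts + 1L, end = ends)
    gc <- as.vector(Biostrings::letterFrequency(vw, "GC")) / (ends - starts)
    out[[ci]] <- data.frame(
      chrom = names(genome)[ci],
      start = starts,
      end = ends,
      left_enzyme = c("CHROM_END", labels),
      right_enzyme = c(labels, "CHROM_END"),
      length = ends - starts,
      gc_fraction = gc,
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), left_enzyme = character(0),
                      right_enzyme = character(0), length = integer(0),
                      gc_fraction = numeric(0)))
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  frags$fragment_id <- paste0(frags$chrom, ":", frags$start, "-", frags$end)
  frags
}

#' Select amplifiable fragments for a library protocol
#'
#' GBS library construction only amplifies fragments that received an
#' adapter at each end, i.e. fragments with an enzyme cut at both ends.
#' The double-digest protocol uses a common (Y) adapter so that only
#' fragments cut by a *different* enzyme at each end amplify.
#'
#' @param fragments Data frame from [digest()].
#' @param protocol `"single"` (one enzyme cut at both ends, e.g. ApeKI) or
#'   `"double_different_ends"` (two distinct enzymes at the two ends, e.g.
#'   PstI:MspI).
#' @return The amplifiable subset of `fragments`.
#' @export
select_amplifiable <- function(fragments,
                               protocol = c("single", "double_different_ends")) {
  protocol <- match.arg(protocol)
  internal <- fragments$left_enzyme != "CHROM_END" &
    fragments$right_enzyme != "CHROM_END"
  keep <- switch(protocol,
    single = internal,
    double_different_ends = internal &
      fragments$left_enzyme != fragments$right_enzyme
  )
  fragments[keep, , drop = FALSE]
}

#' Extract sequencing tags from amplifiable fragments
#'
#' Each amplifiable fragment end yields one tag: the `tag_length` bases read
#' inward from the cut. The right-end tag is reverse-complemented into read
#' orientation. Fragments shorter than `tag_length` are truncated to the
#' insert length (no N-padding; read-through into the adapter is not
#' modelled). For such short fragments the two end reads are exact reverse
#' complements of one another and the right-end duplicate is dropped.
#'
#' @param genome See [as_genome()]; must be the genome `fragments` came from.
#' @param fragments Amplifiable fragments (see [select_amplifiable()]).
#' @param tag_length Tag length in bases (default 64).
#' @return A data frame with one row per tag: `tag_id`, `fragment_id`,
#'   `chrom`, `side` (`"left"`/`"right"`), `sequence`, plus the parent
#'   fragment's `fragment_length` and `fragment_gc` (used by bias models).
#' @export
extract_tags <- function(genome, fragments, tag_length = 64L) {
  tag_length <- as.integer(tag_length)
  if (is.na(tag_length) || tag_length < 1L) stop("tag_length must be >= 1")
  genome <- as_genome(genome)
  if (nrow(fragments) == 0L) {
    return(data.frame(tag_id = character(0), fragment_id = character(0),
                      chrom = character(0), side = character(0),
                      sequence = character(0), fragment_length = integer(0),
                      fragment_gc = numeric(0)))
  }
  res <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    fr <- fragments[fragments$chrom == names(genome)[ci], , drop = FALSE]
    if (nrow(fr) == 0L) next
    chrom_seq <- genome[[ci]]
    short <- fr$length <= tag_length
    l_end <- pmin(fr$start + tag_length, fr$end)
    left_seq <- as.character(Biostrings::Views(chrom_seq,
                                               start = fr$start + 1L,
                                               end = l_end))
    r_start <- pmax(fr$start + 1L, fr$end - tag_length + 1L)
    right_view <- Biostrings::Views(chrom_seq, start = r_start, end = fr$end)
    right_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(right_view)))
    left <- data.frame(
      tag_id = paste0(fr$fragment_id, ":L"),
      fragment_id = fr$fragment_id, chrom = fr$chrom, side = "left",
      sequence = left_seq, fragment_length = fr$length,
      fragment_gc = fr$gc_fraction, stringsAsFactors = FALSE
    )
    right <- data.frame(
      tag_id = paste0(fr$fragment_id, ":R"),
      fragment_id = fr$fragment_id, chrom = fr$chrom, side = "right",
      sequence = right_seq, fragment_length = fr$length,
      fragment_gc = fr$gc_fraction, stringsAsFactors = FALSE
    )[!short, , drop = FALSE]  # short fragments: right read duplicates left
    res[[ci]] <- rbind(left, right)
  }
  tags <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(tags) <- NULL
  tags
}
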