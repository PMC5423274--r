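#' Bin specifications for fragment size and GC spectra
#'
#' `size_bins()` returns the default 15 fragment-size classes: 100-bp bins
#' from 0 to 1400 bp plus one open-ended class above 1400 bp. `gc_bins()`
#' returns the default 7 GC-content classes: five 0.10-wide bins between
#' GC fractions 0.15 and 0.65 plus the two open-ended flanking classes.
#' Edges are configurable; the class counts match the conventional
#' 15-size-class / 7-GC-class presentation of GBS tag spectra, and 0.35 is
#' deliberately an interior edge so that enrichment above versus below 35%
#' GC can be read directly off the spectrum.
#'
#' @param width,max Bin width and upper closed edge for `size_bins()`.
#' @param from,to,n_inner Inner edge range and count for `gc_bins()`.
#' @return An object of class `bin_spec`: a list with `edges` (strictly
#'   increasing, first edge is the lower bound of bin 1, last interval is
#'   open-ended) and `value` (`"length"` or `"gc_fraction"`).
#' @examples
#' size_bins()
#' gc_bins()
#' @export
size_bins <- function(width = 100, max = 1400) {
  bin_spec(c(seq(0, max, by = width), Inf), value = "length")
}

#' @rdname size_bins
#' @export
gc_bins <- function(from = 0.15, to = 0.65, n_inner = 5) {
  bin_spec(c(0, seq(from, to, length.out = n_inner + 1), 1 + 1e-9),
           value = "gc_fraction")
}

#' @rdname size_bins
#' @param edges Strictly increasing numeric vector of bin edges; values at or
#'   above the last finite edge fall in the final (open-ended) bin.
#' @param value Name of the fragment/tag column binned over.
#' @export
bin_spec <- function(edges, value = c("length", "gc_fraction")) {
  value <- match.arg(value)
  stopifnot(is.numeric(edges), length(edges) >= 2L, !is.unsorted(edges),
            !any(duplicated(edges)))
  structure(list(edges = edges, value = value,
                 labels = paste0("[", utils::head(edges, -1L), ",",
                                 utils::tail(edges, -1L), ")")),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat("<bin_spec> ", length(x$labels), " bins over ", x$value, "\n", sep = "")
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

bin_index <- function(values, bins) {
  idx <- findInterval(values, bins$edges, rightmost.closed = FALSE)
  # values below the first edge or beyond the last are clamped into the
  # flanking (open-ended) bins
  pmin(pmax(idx, 1L), length(bins$labels))
}

#' Fragment/tag spectrum over size or GC bins
#'
#' Computes the distribution of fragments or tags across the bins of a
#' [bin_spec()], optionally weighted (e.g. by read counts to obtain an
#' observed spectrum).
#'
#' @param x Data frame of fragments ([digest()]) or tags
#'   ([extract_tags()]); for tags the parent fragment's `fragment_length` /
#'   `fragment_gc` columns are binned, as tags are attributed to the
#'   restriction fragment they come from.
#' @param bins A [bin_spec()].
#' @param weights Optional non-negative weights, one per row of `x`
#'   (default: unweighted counts).
#' @return Data frame with `bin`, `count` (sum of weights) and `frequency`
#'   (normalised to 1 when any mass exists).
#' @export
spectrum <- function(x, bins, weights = NULL) {
  stopifnot(inherits(bins, "bin_spec"))
  col <- if (bins$value == "length") {
    if ("fragment_length" %in% names(x)) "fragment_length" else "length"
  } else {
    if ("fragment_gc" %in% names(x)) "fragment_gc" else "gc_fraction"
  }
  values <- x[[col]]
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights >= 0))
  idx <- bin_index(values, bins)
  count <- vapply(seq_along(bins$labels),
                  function(b) sum(weights[idx == b]), numeric(1))
  total <- sum(count)
  data.frame(bin = bins$labels,
             count = count,
             frequency = if (total > 0) count / total else rep(0, length(count)),
             stringsAsFactors = FALSE)
}

#' Observed versus expected tag spectrum
#'
#' Compares the tag spectrum observed after amplification and sequencing
#' (tags weighted by total read count) with the spectrum expected from the
#' in-silico digestion alone (each tag counted once). Deviations expose
#' polymerase amplification bias over fragment size or GC content.
#'
#' @param tags Tag table from [extract_tags()].
#' @param read_counts Total observed reads per tag (vector aligned with
#'   `tags`, e.g. `rowSums` of a depth table).
#' @param bins A [bin_spec()].
#' @return Data frame with per-bin `expected_pct`, `observed_pct` and
#'   `deviation_pct` (observed minus expected; deviations sum to zero).
#' @export
observed_vs_expected <- function(tags, read_counts, bins) {
  stopifnot(nrow(tags) == length(read_counts))
  expected <- spectrum(tags, bins)
  observed <- spectrum(tags, bins, weights = read_counts)
  data.frame(bin = expected$bin,
             expected_pct = 100 * expected$frequency,
             observed_pct = 100 * observed$frequency,
             deviation_pct = 100 * (observed$frequency - expected$frequency),
             stringsAsFactors = FALSE)
}
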