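IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its name, an IUPAC recognition
#' sequence (degenerate codes such as `W` = A/T are allowed), and the cut
#' offset: the number of bases from the start of the recognition site to the
#' cut position on the top strand. For example ApeKI (`G^CWGC`) has
#' recognition `"GCWGC"` and `cut_offset = 1`.
#'
#' Only enzymes whose recognition site is its own reverse complement under
#' IUPAC semantics (a degenerate palindrome) are accepted, so that scanning
#' the top strand finds every site. Non-palindromic enzymes would require
#' double-strand scanning and are rejected at construction time.
#'
#' @param name Enzyme name, e.g. `"ApeKI"`.
#' @param recognition IUPAC recognition sequence, e.g. `"GCWGC"`.
#' @param cut_offset Bases from the recognition-site start to the cut, in
#'   `[0, nchar(recognition)]`.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("ApeKI", "GCWGC", 1)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(recognition)
  stopifnot(is.character(recognition), length(recognition) == 1L,
            nzchar(recognition))
  letters_ <- strsplit(recognition, "")[[1]]
  bad <- setdiff(letters_, names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s) in recognition sequence for ", name, ": ",
         paste(unique(bad), collapse = ", "))
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie in [0, ", nchar(recognition), "] for ", name)
  }
  rc <- paste(rev(unname(IUPAC_COMPLEMENT[letters_])), collapse = "")
  if (!identical(rc, recognition)) {
    stop("recognition site of ", name, " (", recognition,
         ") is not a degenerate palindrome; only palindromic sites are ",
         "supported (top-strand scanning)")
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat("<restriction_enzyme> ", x$name, ": ", site, "\n", sep = "")
  invisible(x)
}

#' Load restriction enzyme definitions from a YAML file
#'
#' Enzyme definitions are shipped as editable configuration rather than code.
#' The packaged default file provides ApeKI (`G^CWGC`), PstI (`CTGCA^G`),
#' MspI (`C^CGG`) and the toy enzyme EcoRI (`G^AATTC`).
#'
#' @param path Path to a YAML file: a list of entries with `name`,
#'   `recognition` and `cut_offset`. Defaults to the packaged definitions.
#' @return Named list of [restriction_enzyme()] objects.
#' @examples
#' enzymes <- load_enzymes()
#' enzymes$ApeKI
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.yaml",
                                            package = "gbsdesign")) {
  entries <- yaml::read_yaml(path)
  enz <- lapply(entries, function(e) {
    restriction_enzyme(e$name, e$recognition, e$cut_offset)
  })
  stats::setNames(enz, vapply(enz, `[[`, character(1), "name"))
}

#' Convert an IUPAC recognition sequence to a regular expression
#'
#' Used by the brute-force site scanner that serves as an independent check
#' of the digestion engine.
#'
#' @param recognition IUPAC string.
#' @return A regular expression character class string.
#' @keywords internal
#' @export
iupac_to_regex <- function(recognition) {
  letters_ <- strsplit(toupper(recognition), "")[[1]]
  paste(vapply(letters_, function(l) {
    opts <- IUPAC_CODES[[l]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}
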