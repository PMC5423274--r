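#' Read and write genome FASTA files
#'
#' Thin wrappers over Biostrings that accept multi-record, wrapped or
#' unwrapped FASTA.
#'
#' @param path File path.
#' @return `read_genome_fasta` returns a named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_genome_fasta
#' @param genome See [as_genome()].
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Write a tab-separated table
#'
#' All tabular artifacts are written as TSV so runs are diffable.
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @param row_names Column name under which to store row names, or `NULL`
#'   to drop them.
#' @export
write_tsv_table <- function(x, path, row_names = NULL) {
  if (!is.null(row_names)) {
    x <- data.frame(stats::setNames(list(rownames(x)), row_names),
                    as.data.frame(x), check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write marker matrices as TSV
#'
#' Marker matrices are stored with genotypes in rows and loci in columns,
#' codes 0/1/2 and `NA` for missing; the first column holds genotype
#' identifiers.
#'
#' @param calls Genotype x locus matrix.
#' @param path File path.
#' @export
write_marker_matrix <- function(calls, path) {
  write_tsv_table(calls, path, row_names = "genotype")
}

#' @rdname write_marker_matrix
#' @return `read_marker_matrix` returns an integer matrix with genotype row
#'   names.
#' @export
read_marker_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Read and write phenotype vectors as TSV
#'
#' Two columns: `genotype` and `value`.
#'
#' @param y Named numeric vector.
#' @param path File path.
#' @export
write_phenotypes <- function(y, path) {
  write_tsv_table(data.frame(genotype = names(y), value = as.numeric(y)),
                  path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(df$value, df$genotype)
}
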