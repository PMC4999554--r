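#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings' parsers that return the package's
#' sequence-record representation (named uppercase character vector, see
#' [seq_records()]).  Record order and ids are preserved; wrapped and
#' unwrapped files are read identically.
#'
#' @param path file path
#' @param alphabet `"nucleotide"`, `"protein"` or `NULL` to guess
#' @return named character vector of sequences
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    warning("no records in ", path, call. = FALSE)
    return(seq_records(character(0), alphabet = alphabet))
  }
  ids <- sub("\\s.*$", "", names(set))
  seq_records(as.character(set), ids = ids, alphabet = alphabet)
}

#' @rdname read_fasta
#' @param x named character vector of sequences
#' @param width line-wrap width for sequence lines
#' @export
write_fasta <- function(x, path, width = 60L) {
  set <- Biostrings::BStringSet(setNames(as.character(x), names(x)))
  Biostrings::writeXStringSet(set, path, width = width, format = "fasta")
  invisible(path)
}

#' Read and write FASTQ (Phred+33)
#'
#' Qualities are retained as a `"qualities"` attribute (character vector of
#' Phred+33 strings) but are not used by downstream classification.
#'
#' @inheritParams read_fasta
#' @return named character vector of read sequences with attribute
#'   `qualities`
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    list(set = set,
         qual = as.character(S4Vectors::mcols(set)$qualities))
  }, error = function(e)
    stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  set <- parsed$set
  if (length(set) == 0L) {
    warning("no records in ", path, call. = FALSE)
    return(structure(seq_records(character(0)), qualities = character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  qual <- parsed$qual
  bad <- nchar(qual) != nchar(as.character(set))
  if (any(bad))
    stop("FASTQ record ", which(bad)[1], " (", ids[which(bad)[1]],
         "): sequence and quality lengths differ", call. = FALSE)
  out <- seq_records(as.character(set), ids = ids, alphabet = "nucleotide")
  attr(out, "qualities") <- qual
  out
}

#' @rdname read_fastq
#' @param x named character vector of read sequences
#' @param qualities Phred+33 strings; defaults to the `"qualities"`
#'   attribute of `x`, or uniform `"I"` (Q40)
#' @export
write_fastq <- function(x, path, qualities = attr(x, "qualities")) {
  if (is.null(qualities))
    qualities <- vapply(nchar(x), function(n)
      paste(rep("I", n), collapse = ""), character(1))
  stopifnot(length(qualities) == length(x),
            all(nchar(qualities) == nchar(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(x), "\n", as.character(x), "\n+\n", qualities),
             con, sep = "\n")
  invisible(path)
}

#' Write a tabular report as TSV
#'
#' Deterministic output: fixed column order (as given), floating-point
#' columns printed with 6 decimals, no quoting.
#'
#' @param table a data.frame with a non-empty header
#' @param path output file
#' @return `path`, invisibly
#' @export
write_report <- function(table, path) {
  stopifnot(is.data.frame(table), ncol(table) > 0)
  out <- table
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6f", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
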