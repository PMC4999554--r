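#' Sequence records
#'
#' Throughout the package a set of sequences is a named character vector of
#' uppercase residues: DNA over `A,C,G,T,N` or protein over the 20 amino
#' acids plus `X` (unknown) and `*` (stop).  Names are the record ids.
#'
#' @param residues character vector of residue strings
#' @param ids record ids; defaults to existing names
#' @param alphabet `"nucleotide"` or `"protein"`; guessed when `NULL`
#' @return a named character vector with attribute `alphabet`
#' @export
#' @examples
#' seq_records(c("ACGT", "TTGA"), ids = c("s1", "s2"))
seq_records <- function(residues, ids = names(residues), alphabet = NULL) {
  if (length(residues) == 0L)
    return(structure(character(0), alphabet = alphabet %||% "nucleotide"))
  residues <- toupper(as.character(residues))
  if (any(!nzchar(residues)))
    stop("sequence records must be non-empty", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(residues))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (is.null(alphabet)) alphabet <- guess_alphabet(residues)
  alphabet <- match.arg(alphabet, c("nucleotide", "protein"))
  bad <- !grepl(alphabet_regex(alphabet), residues)
  if (any(bad))
    stop("record(s) ", paste(ids[bad], collapse = ", "),
         " contain characters outside the ", alphabet, " alphabet",
         call. = FALSE)
  structure(setNames(residues, ids), alphabet = alphabet)
}

alphabet_regex <- function(alphabet) {
  if (alphabet == "nucleotide") "^[ACGTN]+$" else "^[ACDEFGHIKLMNPQRSTVWYX*]+$"
}

#' @rdname seq_records
#' @param x character vector of residue strings
#' @export
guess_alphabet <- function(x) {
  if (all(grepl("^[ACGTN]*$", toupper(x)))) "nucleotide" else "protein"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide sequences
#'
#' @param x character vector of DNA strings (`A,C,G,T,N`)
#' @return character vector of the same length
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# codon table (standard genetic code), taken from Biostrings at load time
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate a nucleotide sequence
#'
#' Standard-code translation in a fixed frame.  Stops are rendered `*`, a
#' trailing partial codon is dropped, and any codon containing a character
#' other than `A,C,G,T` translates to `X`.
#'
#' @param nt a DNA string (length-1 character)
#' @param frame reading frame, 1, 2 or 3
#' @return a protein string of length `floor((nchar(nt) - frame + 1) / 3)`
#' @export
#' @examples
#' translate_sequence("ATGAAATAG")  # "MK*"
translate_sequence <- function(nt, frame = 1L) {
  stopifnot(length(nt) == 1L, frame %in% 1:3)
  nt <- toupper(nt)
  if (!grepl("^[ACGTN]*$", nt))
    stop("translate_sequence() requires a nucleotide sequence", call. = FALSE)
  s <- substring(nt, frame)
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codons)
  codons <- substring(s, starts, starts + 2L)
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# strip alignment gaps
ungap <- function(x) gsub("-", "", x, fixed = TRUE)
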