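#' Alignment scoring schemes
#'
#' Affine-gap scoring used by [global_align()].  A gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`; both penalties are non-positive.
#' Nucleotide scoring defaults to match +1 / mismatch -1 with gap open -5
#' and extend -2: the extension penalty is kept above the mismatch cost so
#' that alignments of diverged sequences stay substitution-dominated rather
#' than degenerating into gap mosaics that inflate apparent identity.
#' Protein scoring defaults to BLOSUM62 with gap open -11 and extend -1.
#'
#' @param alphabet `"nucleotide"` or `"protein"`
#' @param match,mismatch nucleotide match reward / mismatch penalty
#'   (ignored when `submat` is given)
#' @param gap_open,gap_extend gap penalties (must be <= 0)
#' @param submat optional symmetric substitution matrix with residue
#'   dimnames; defaults to BLOSUM62 for proteins
#' @return an object of class `scoring_scheme`
#' @export
#' @examples
#' scoring_scheme("nucleotide")
#' scoring_scheme("protein")$gap_open
scoring_scheme <- function(alphabet = c("nucleotide", "protein"),
                           match = 1, mismatch = -1,
                           gap_open = NULL, gap_extend = NULL,
                           submat = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(gap_open))   gap_open   <- if (alphabet == "nucleotide") -5 else -11
  if (is.null(gap_extend)) gap_extend <- if (alphabet == "nucleotide") -2 else -1
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be <= 0", call. = FALSE)
  if (is.null(submat)) {
    if (alphabet == "nucleotide") {
      letters <- c("A", "C", "G", "T", "N")
      submat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
      diag(submat) <- match
      # ambiguity scores as mismatch, even against itself
      submat["N", ] <- mismatch
      submat[, "N"] <- mismatch
    } else {
      submat <- blosum62()
    }
  }
  if (!isTRUE(all.equal(submat, t(submat))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  structure(list(alphabet = alphabet, submat = submat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# BLOSUM62 values, via Biostrings' packaged copy
blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$alphabet,
      ": gap open ", x$gap_open, ", extend ", x$gap_extend, "\n", sep = "")
  invisible(x)
}

encode_for <- function(seq, scheme) {
  letters <- rownames(scheme$submat)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, letters)
  fallback <- match(if (scheme$alphabet == "nucleotide") "N" else "X", letters)
  idx[is.na(idx)] <- fallback
  idx - 1L
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (Gotoh), or overlap
#' alignment in which `a` is aligned end to end while terminal gaps in `b`
#' are free — the read-mapping case, with `a` the read and `b` the
#' reference window it falls in.  Traceback tie-breaking is fixed
#' (diagonal, then up, then left) so results are bit-reproducible.
#'
#' @param a,b residue strings (length-1 character, optionally named) or
#'   single records from [seq_records()]
#' @param scoring a [scoring_scheme()]; defaults to the alphabet's default
#' @param type `"global"`, or `"overlap"` (`a` global, `b`'s terminal gaps
#'   free)
#' @param mode identity denominator, see [percent_identity()]
#' @return an object of class `pairwise_alignment` with elements
#'   `aligned_a`, `aligned_b` (gapped strings), `score`, `matches`,
#'   `columns` and `identity`
#' @export
#' @examples
#' aln <- global_align("ACGT", "AGT")
#' aln$identity
global_align <- function(a, b, scoring = NULL,
                         type = c("global", "overlap"),
                         mode = c("exclude-terminal-gaps", "all-columns")) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  id_a <- names(a) %||% "a"; id_b <- names(b) %||% "b"
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b))
    stop("cannot align empty sequences", call. = FALSE)
  alph_a <- guess_alphabet(a); alph_b <- guess_alphabet(b)
  if (alph_a != alph_b)
    stop("alphabet mismatch: one sequence is nucleotide, the other protein",
         call. = FALSE)
  if (is.null(scoring)) scoring <- scoring_scheme(alph_a)
  # a pure-ACGT string is also a valid protein string; only a protein
  # sequence under a nucleotide scheme is a real clash
  if (scoring$alphabet == "nucleotide" && alph_a == "protein")
    stop("sequence alphabet does not match the scoring scheme", call. = FALSE)

  res <- .align_core(encode_for(a, scoring), encode_for(b, scoring),
                     scoring$submat, scoring$gap_open, scoring$gap_extend,
                     type == "overlap")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ga <- ifelse(is.na(res$ia), "-", ca[res$ia])
  gb <- ifelse(is.na(res$ib), "-", cb[res$ib])
  out <- structure(
    list(id_a = id_a, id_b = id_b,
         aligned_a = paste(ga, collapse = ""),
         aligned_b = paste(gb, collapse = ""),
         score = res$score,
         alphabet = scoring$alphabet,
         columns = length(ga),
         matches = count_matches(ga, gb, scoring$alphabet),
         identity = NA_real_),
    class = "pairwise_alignment")
  # an overlap alignment may legitimately align nothing (all columns in
  # terminal gaps) when the sequences are unrelated; identity is 0 then
  out$identity <- if (type == "overlap")
    tryCatch(percent_identity(out, mode), error = function(e) 0)
  else percent_identity(out, mode)
  out
}

# residue-equal columns; gaps and ambiguity codes (N / X) never match
count_matches <- function(ga, gb, alphabet) {
  amb <- if (alphabet == "nucleotide") "N" else "X"
  sum(ga == gb & ga != "-" & ga != amb)
}

#' Percent identity of a pairwise alignment
#'
#' Matches divided by a column count.  `"all-columns"` uses every alignment
#' column; `"exclude-terminal-gaps"` (the default used by the clade-typing
#' threshold) drops leading and trailing gap runs first so that partial
#' sequences are not penalised for length differences.
#'
#' @param aln a `pairwise_alignment`
#' @param mode denominator definition
#' @return identity as a fraction in \[0, 1\]
#' @export
#' @examples
#' percent_identity(global_align("ACGT", "ACGT"), "all-columns")
percent_identity <- function(aln,
                             mode = c("exclude-terminal-gaps", "all-columns")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "pairwise_alignment"))
  ga <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  gb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, length(ga))
  if (mode == "exclude-terminal-gaps") {
    gap <- ga == "-" | gb == "-"
    inner <- which(!gap)
    if (length(inner) == 0L)
      stop("alignment has no gap-free columns; identity undefined",
           call. = FALSE)
    keep <- seq_along(ga) >= min(inner) & seq_along(ga) <= max(inner)
  }
  denom <- sum(keep)
  if (denom == 0L)
    stop("identity denominator is zero", call. = FALSE)
  count_matches(ga[keep], gb[keep], aln$alphabet) / denom
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat("<pairwise_alignment> ", x$id_a, " vs ", x$id_b,
      ": score ", format(x$score), ", identity ",
      sprintf("%.3f", x$identity), " over ", x$columns, " columns\n",
      sep = "")
  n <- nchar(x$aligned_a)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    cat(substr(x$aligned_a, s, e), "\n", substr(x$aligned_b, s, e), "\n\n",
        sep = "")
  }
  invisible(x)
}

#' Export an alignment as two-row FASTA
#'
#' @param aln a `pairwise_alignment`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  writeLines(c(paste0(">", aln$id_a), aln$aligned_a,
               paste0(">", aln$id_b), aln$aligned_b), path)
  invisible(path)
}
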