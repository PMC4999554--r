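#' Call variants in an isolate PIP gene against the reference
#'
#' The isolate sequence (assembled or Sanger-grade, not raw reads) is
#' globally aligned to the reference coding sequence.  Every mismatch
#' column becomes a SNP; every gap run becomes an insertion or deletion,
#' left-aligned in homopolymer context (VCF convention) so positions are
#' deterministic.  Insertions at or above `is_floor` nucleotides are
#' reported as IS-insertions (insertion-sequence-like cassettes).
#'
#' Coordinates are 1-based on the reference: a SNP or deletion position is
#' its first affected base; an insertion position is the reference base
#' immediately 5' of the inserted run (0 for an insertion before base 1).
#'
#' @param isolate isolate gene sequence (length-1 named character)
#' @param reference reference coding sequence (length-1 named character)
#' @param is_floor minimum insertion length called as an IS-insertion
#' @param anchor optional [reference_anchor()] used to flag calls inside
#'   the variable region; defaults to the reference's nt 1024-1482 window
#'   when the reference is at least that long
#' @return data.frame of class `variant_calls` with columns `type`
#'   (`SNP`, `insertion`, `deletion`, `IS-insertion`), `pos`, `ref`,
#'   `alt`, `in_variable_region`, sorted by position
#' @export
call_variants <- function(isolate, reference, is_floor = 500L,
                          anchor = NULL) {
  stopifnot(length(isolate) == 1L, length(reference) == 1L)
  ref <- toupper(as.character(reference))
  iso <- toupper(as.character(isolate))
  aln <- global_align(iso, ref, scoring = scoring_scheme("nucleotide"))
  if (aln$identity < 0.5)
    stop("isolate is not comparable to the reference (identity ",
         sprintf("%.2f", aln$identity), " < 0.5)", call. = FALSE)
  gq <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]  # isolate
  gr <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]  # reference
  refpos <- cumsum(gr != "-")
  vr <- if (!is.null(anchor)) anchor$vr_nt
        else if (nchar(ref) >= 1482L) c(1024L, 1482L) else c(NA, NA)

  calls <- list()
  add <- function(type, pos, refa, alta) {
    calls[[length(calls) + 1L]] <<- list(type = type, pos = pos,
                                         ref = refa, alt = alta)
  }
  n <- length(gq)
  i <- 1L
  while (i <= n) {
    if (gr[i] == "-") {               # insertion run (gap in reference)
      j <- i
      while (j < n && gr[j + 1L] == "-") j <- j + 1L
      ins <- paste(gq[i:j], collapse = "")
      add("insertion", refpos[i], "", ins)   # refpos[i] = base 5' of run
      i <- j + 1L
    } else if (gq[i] == "-") {        # deletion run (gap in isolate)
      j <- i
      while (j < n && gq[j + 1L] == "-") j <- j + 1L
      del <- paste(gr[i:j], collapse = "")
      add("deletion", refpos[i], del, "")
      i <- j + 1L
    } else {
      if (gq[i] != gr[i]) add("SNP", refpos[i], gr[i], gq[i])
      i <- i + 1L
    }
  }
  if (length(calls) == 0L) {
    out <- data.frame(type = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      in_variable_region = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("variant_calls", "data.frame")
    return(out)
  }
  out <- data.frame(
    type = vapply(calls, `[[`, character(1), "type"),
    pos = vapply(calls, function(x) as.integer(x$pos), integer(1)),
    ref = vapply(calls, `[[`, character(1), "ref"),
    alt = vapply(calls, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE)

  # left-align indels through homopolymer context (VCF convention)
  for (k in seq_len(nrow(out))) {
    if (out$type[k] == "insertion") {
      norm <- left_align_indel(ref, "insertion", out$pos[k], out$alt[k])
      out$pos[k] <- norm$pos; out$alt[k] <- norm$allele
    } else if (out$type[k] == "deletion") {
      norm <- left_align_indel(ref, "deletion", out$pos[k], out$ref[k])
      out$pos[k] <- norm$pos; out$ref[k] <- norm$allele
    }
  }
  out$type[out$type == "insertion" & nchar(out$alt) >= is_floor] <-
    "IS-insertion"
  out$in_variable_region <- if (is.na(vr[1])) NA else vapply(
    seq_len(nrow(out)), function(k) {
      span <- variant_span(out$type[k], out$pos[k], out$ref[k])
      span[2] >= vr[1] && span[1] <= vr[2]
    }, logical(1))
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

# shift an indel leftward through repeated context so its position is the
# canonical (leftmost) one; returns list(pos, allele)
left_align_indel <- function(ref, type, pos, allele) {
  L <- nchar(allele)
  if (L == 0L) return(list(pos = pos, allele = allele))
  if (type %in% c("insertion", "IS-insertion")) {
    while (pos >= 1L && substr(ref, pos, pos) == substr(allele, L, L)) {
      allele <- paste0(substr(ref, pos, pos), substr(allele, 1L, L - 1L))
      pos <- pos - 1L
    }
  } else {
    while (pos > 1L &&
           substr(ref, pos - 1L, pos - 1L) == substr(allele, L, L)) {
      pos <- pos - 1L
      allele <- paste0(substr(ref, pos, pos), substr(allele, 1L, L - 1L))
    }
  }
  list(pos = pos, allele = allele)
}

# reference footprint of a call; an insertion sits between pos and pos+1
variant_span <- function(type, pos, ref) {
  if (type %in% c("insertion", "IS-insertion")) c(pos, pos + 1L)
  else if (type == "deletion") c(pos, pos + nchar(ref) - 1L)
  else c(pos, pos)
}

# apply a single call to the reference sequence
apply_variant <- function(reference, type, pos, ref_allele, alt_allele) {
  s <- as.character(reference)
  if (type == "SNP") {
    paste0(substr(s, 1, pos - 1), alt_allele,
           substr(s, pos + 1, nchar(s)))
  } else if (type %in% c("insertion", "IS-insertion")) {
    paste0(substr(s, 1, pos), alt_allele, substr(s, pos + 1, nchar(s)))
  } else {
    paste0(substr(s, 1, pos - 1),
           substr(s, pos + nchar(ref_allele), nchar(s)))
  }
}

#' Annotate the coding consequence of variant calls
#'
#' SNPs are classified by codon translation (synonymous, missense or
#' nonsense when a premature stop is created); insertions and deletions by
#' net length modulo three (frameshift vs in-frame-indel); IS-insertions
#' as IS-disruption.  For nonsense and frameshift calls the truncated
#' product length is the number of residues translated before the first
#' novel stop after applying the call to the reference.
#'
#' @param calls a `variant_calls` data.frame from [call_variants()]
#' @param reference the reference coding sequence the calls were made
#'   against (must begin at the ORF start)
#' @return `calls` with added columns `consequence`, `codon`,
#'   `truncated_length`
#' @export
annotate_consequence <- function(calls, reference) {
  stopifnot(inherits(calls, "variant_calls"))
  ref <- toupper(as.character(reference))
  n_codons <- nchar(ref) %/% 3L
  if (nrow(calls) > 0 && any(calls$pos > nchar(ref) | calls$pos < 0L))
    stop("variant position outside the reference", call. = FALSE)

  consequence <- character(nrow(calls))
  codon <- integer(nrow(calls))
  trunc_len <- rep(NA_integer_, nrow(calls))
  for (k in seq_len(nrow(calls))) {
    type <- calls$type[k]; pos <- calls$pos[k]
    codon[k] <- max(1L, as.integer(ceiling(pos / 3)))
    if (type == "SNP") {
      cstart <- 3L * (codon[k] - 1L) + 1L
      ref_codon <- substr(ref, cstart, cstart + 2L)
      mutated <- apply_variant(ref, "SNP", pos, calls$ref[k], calls$alt[k])
      alt_codon <- substr(mutated, cstart, cstart + 2L)
      ref_aa <- translate_sequence(ref_codon)
      alt_aa <- translate_sequence(alt_codon)
      if (alt_aa == ref_aa) {
        consequence[k] <- "synonymous"
      } else if (alt_aa == "*" && codon[k] < n_codons) {
        consequence[k] <- "nonsense"
        trunc_len[k] <- codon[k] - 1L
      } else {
        consequence[k] <- "missense"
      }
    } else if (type == "IS-insertion") {
      consequence[k] <- "IS-disruption"
      codon[k] <- as.integer(ceiling((pos + 1L) / 3))
    } else {
      net <- nchar(calls$alt[k]) - nchar(calls$ref[k])
      if (net %% 3L != 0L) {
        consequence[k] <- "frameshift"
        mutated <- apply_variant(ref, type, pos, calls$ref[k], calls$alt[k])
        prot <- translate_sequence(mutated)
        stop_at <- regexpr("*", prot, fixed = TRUE)
        if (stop_at > 0) trunc_len[k] <- as.integer(stop_at) - 1L
      } else {
        consequence[k] <- "in-frame-indel"
      }
      if (type == "insertion") codon[k] <- as.integer(ceiling((pos + 1L) / 3))
    }
  }
  calls$consequence <- consequence
  calls$codon <- codon
  calls$truncated_length <- trunc_len
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

#' Classify the predicted phage-resistance genotype of an isolate
#'
#' An isolate is predicted resistant when it carries at least one
#' loss-of-function lesion — nonsense, frameshift or IS-disruption — or a
#' deletion overlapping the variable region (truncations there abolish
#' infectivity regardless of position).  Missense-only genotypes are
#' predicted sensitive but flagged for review.
#'
#' @param variants an annotated `variant_calls` data.frame
#'   (see [annotate_consequence()])
#' @param anchor a [reference_anchor()] giving the variable-region window
#' @param isolate_id label for the isolate
#' @return an object of class `isolate_genotype`: `isolate_id`,
#'   `variants`, `phenotype` (`"resistant"` or `"sensitive"`), `reason`
#' @export
classify_resistance <- function(variants, anchor = reference_anchor(),
                                isolate_id = "isolate") {
  stopifnot(inherits(variants, "variant_calls"))
  if (!"consequence" %in% names(variants))
    stop("variants must be annotated first (annotate_consequence)",
         call. = FALSE)
  vr <- anchor$vr_nt
  phenotype <- "sensitive"
  reason <- "no loss-of-function lesion"
  lof <- which(variants$consequence %in%
                 c("nonsense", "frameshift", "IS-disruption"))
  if (length(lof) > 0) {
    k <- lof[1]
    phenotype <- "resistant"
    reason <- switch(variants$consequence[k],
      "IS-disruption" = paste0("IS insertion at nt ", variants$pos[k]),
      "nonsense" = paste0("premature stop at codon ", variants$codon[k]),
      paste0("frameshift at nt ", variants$pos[k]))
  } else {
    del_vr <- which(variants$type == "deletion" &
                      vapply(seq_len(nrow(variants)), function(k) {
                        span <- variant_span(variants$type[k],
                                             variants$pos[k],
                                             variants$ref[k])
                        span[2] >= vr[1] && span[1] <= vr[2]
                      }, logical(1)))
    if (length(del_vr) > 0) {
      phenotype <- "resistant"
      reason <- paste0("deletion truncating the variable region at nt ",
                       variants$pos[del_vr[1]])
    } else if (any(variants$consequence == "missense")) {
      reason <- "missense only; flagged for review"
    }
  }
  structure(list(isolate_id = isolate_id, variants = variants,
                 phenotype = phenotype, reason = reason),
            class = "isolate_genotype")
}

#' @export
print.isolate_genotype <- function(x, ...) {
  cat("<isolate_genotype> ", x$isolate_id, ": ", x$phenotype, " (",
      x$reason, "), ", nrow(x$variants), " variant(s)\n", sep = "")
  invisible(x)
}
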