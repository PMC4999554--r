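#' Classify variable-region amplicon reads against clade representatives
#'
#' Each read is aligned to every clade representative in both orientations
#' (the better orientation per representative is kept) using overlap
#' alignment, since a 250-nt read covers only part of the 459-nt variable
#' region; identity is computed over the terminal-gap-free columns.  A read
#' is assigned to the best-identity clade when that identity reaches
#' `min_identity` and the margin to the second-best clade reaches
#' `min_margin`; exact ties are ambiguous and left `"unassigned"`.
#'
#' @param reads named character vector of nucleotide reads
#' @param scheme a [clade_scheme()] with nucleotide-level representatives
#' @param min_identity minimum identity for assignment (default 0.90,
#'   deliberately below the 0.95 clade threshold to tolerate sequencing
#'   error)
#' @param min_margin minimum identity gap to the second-best clade
#' @return data.frame with columns `read_id`, `clade` (or
#'   `"unassigned"`), `identity`, `margin`
#' @export
classify_reads <- function(reads, scheme, min_identity = 0.90,
                           min_margin = 0) {
  stopifnot(inherits(scheme, "clade_scheme"))
  if (length(reads) == 0L) stop("empty read set", call. = FALSE)
  if (is.null(scheme$representatives))
    stop("scheme has no representative sequences", call. = FALSE)
  if (scheme$level != "nucleotide")
    stop("read classification needs nucleotide-level representatives",
         call. = FALSE)
  scoring <- scoring_scheme("nucleotide")
  reps <- scheme$representatives
  ids <- names(reads) %||% paste0("read", seq_along(reads))

  one <- function(read) {
    rc <- reverse_complement(read)
    per_rep <- vapply(reps, function(rep) {
      max(global_align(read, rep, scoring = scoring,
                       type = "overlap")$identity,
          global_align(rc, rep, scoring = scoring,
                       type = "overlap")$identity)
    }, numeric(1))
    ord <- order(-per_rep)
    best <- per_rep[ord[1]]
    second <- if (length(per_rep) > 1) per_rep[ord[2]] else -Inf
    margin <- if (is.finite(second)) best - second else Inf
    clade <- names(per_rep)[ord[1]]
    if (best < min_identity || margin < min_margin || margin == 0)
      clade <- "unassigned"
    list(clade = clade, identity = unname(best), margin = unname(margin))
  }
  res <- lapply(as.character(reads), one)
  data.frame(read_id = ids,
             clade = vapply(res, `[[`, character(1), "clade"),
             identity = vapply(res, `[[`, numeric(1), "identity"),
             margin = vapply(res, `[[`, numeric(1), "margin"),
             stringsAsFactors = FALSE)
}

#' Summarise clade abundance from read assignments
#'
#' Per-clade read counts and fractions of assigned reads; unassigned reads
#' are reported separately and excluded from the fractions.
#'
#' @param assignments data.frame from [classify_reads()] (one sample)
#' @param clades optional character vector of clade ids to report (zero
#'   counts included); defaults to the clades observed
#' @return an object of class `clade_abundance`: a data.frame
#'   (`clade`, `count`, `fraction`) with attributes `unassigned` and
#'   `total`
#' @export
summarize_abundance <- function(assignments, clades = NULL) {
  stopifnot(is.data.frame(assignments), "clade" %in% names(assignments))
  assigned <- assignments$clade[assignments$clade != "unassigned"]
  if (is.null(clades)) clades <- sort(unique(assigned))
  counts <- vapply(clades, function(cl) sum(assigned == cl), integer(1))
  n_assigned <- length(assigned)
  if (n_assigned == 0L) {
    warning("no reads were assigned to any clade", call. = FALSE)
    fractions <- rep(NA_real_, length(clades))
  } else {
    fractions <- counts / n_assigned
  }
  out <- data.frame(clade = as.character(clades), count = unname(counts),
                    fraction = unname(fractions), stringsAsFactors = FALSE)
  structure(out,
            unassigned = nrow(assignments) - n_assigned,
            total = nrow(assignments),
            class = c("clade_abundance", "data.frame"))
}

#' Per-position amino-acid variant profile against the reference
#'
#' Aligns each nucleotide sequence (read or contig) to the reference
#' variable region, translates it codon-by-codon in the reference frame,
#' and accumulates observed residues per reference amino-acid position
#' (342-494).  Sequences that do not overlap the region are skipped, and
#' sequences whose aligned span carries a net indel not divisible by three
#' are flagged frameshifted and excluded, since they cannot be read in the
#' reference frame.
#'
#' @param sequences named character vector of nucleotide reads or contigs
#' @param anchor a [reference_anchor()]
#' @return data.frame with columns `position`, `ref_aa`, `coverage`,
#'   `variant_fraction`, `top_alt`; attributes `residue_counts` (matrix
#'   position x residue) and `excluded` (data.frame id, reason)
#' @export
variant_profile <- function(sequences, anchor) {
  stopifnot(inherits(anchor, "reference_anchor"))
  ref_region <- substr(as.character(anchor$gene), anchor$vr_nt[1],
                       anchor$vr_nt[2])
  ref_aa <- strsplit(translate_sequence(ref_region), "", fixed = TRUE)[[1]]
  positions <- seq(anchor$vr_aa[1], anchor$vr_aa[2])
  stopifnot(length(ref_aa) == length(positions))
  aa_letters <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
  counts <- matrix(0L, nrow = length(positions), ncol = length(aa_letters),
                   dimnames = list(positions, aa_letters))
  excluded <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  scoring <- scoring_scheme("nucleotide")
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))

  for (k in seq_along(sequences)) {
    seq_fwd <- as.character(sequences[[k]])
    aln_f <- global_align(seq_fwd, ref_region, scoring = scoring,
                          type = "overlap")
    aln_r <- global_align(reverse_complement(seq_fwd), ref_region,
                          scoring = scoring, type = "overlap")
    aln <- if (aln_r$identity > aln_f$identity) aln_r else aln_f
    gq <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]  # query
    gr <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]  # reference region
    inner <- which(gq != "-" & gr != "-")
    if (length(inner) == 0L || aln$identity < 0.5) {
      warning("skipping ", ids[k], ": does not overlap the variable region",
              call. = FALSE)
      excluded <- rbind(excluded, data.frame(id = ids[k],
                                             reason = "no overlap"))
      next
    }
    span <- seq(min(inner), max(inner))
    net_indel <- sum(gr[span] == "-") - sum(gq[span] == "-")
    if (net_indel %% 3L != 0L) {
      excluded <- rbind(excluded, data.frame(id = ids[k],
                                             reason = "frameshift"))
      next
    }
    refpos <- cumsum(gr != "-")
    # codon c of the region occupies reference-region nt 3c-2 .. 3c
    for (codon in seq_along(positions)) {
      cols <- which(refpos %in% (3L * codon - 2L):(3L * codon) & gr != "-")
      if (length(cols) != 3L) next
      if (any(gq[cols] == "-")) next               # deletion in query
      if (max(cols) - min(cols) != 2L) next        # insertion inside codon
      aa <- translate_sequence(paste(gq[cols], collapse = ""))
      counts[codon, aa] <- counts[codon, aa] + 1L
    }
  }
  coverage <- rowSums(counts)
  ref_count <- counts[cbind(seq_along(positions),
                            match(ref_aa, aa_letters))]
  variant_fraction <- ifelse(coverage > 0,
                             (coverage - ref_count) / coverage, NA_real_)
  top_alt <- vapply(seq_along(positions), function(i) {
    alt <- counts[i, ]
    alt[match(ref_aa[i], aa_letters)] <- 0L
    if (sum(alt) == 0L) NA_character_ else aa_letters[which.max(alt)]
  }, character(1))
  structure(data.frame(position = positions, ref_aa = ref_aa,
                       coverage = as.integer(coverage),
                       variant_fraction = variant_fraction,
                       top_alt = top_alt, stringsAsFactors = FALSE),
            residue_counts = counts, excluded = excluded,
            class = c("position_variant_profile", "data.frame"))
}
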