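#' Reference anchor for variable-region extraction
#'
#' The PIP gene of E. faecalis V583 (locus EF0858) carries a hypervariable
#' region at amino acids 342-494 of the 888-residue protein, i.e.
#' nucleotides 1024-1482 of the coding sequence by codon arithmetic
#' (`start_nt = 3 * start_aa - 2`, `end_nt = 3 * end_aa`).  An anchor
#' bundles the full-length reference gene, its translation and those
#' coordinates.
#'
#' The packaged default reference is a *synthetic* stand-in with the real
#' gene's geometry (2667-nt ORF, 888 aa + stop, variable region at the
#' coordinates above); see `inst/extdata/synthetic_v583_pipef.fasta`.
#' Supply the real EF0858 sequence via `gene` to anchor on it instead.
#'
#' @param gene full-length reference coding sequence (named character of
#'   length 1); `NULL` loads the packaged synthetic reference
#' @param vr_aa 1-based inclusive amino-acid bounds of the variable region
#' @return an object of class `reference_anchor` with elements `gene`,
#'   `protein`, `vr_aa` and `vr_nt`
#' @export
#' @examples
#' anchor <- reference_anchor()
#' anchor$vr_nt
reference_anchor <- function(gene = NULL, vr_aa = c(342L, 494L)) {
  if (is.null(gene)) {
    path <- system.file("extdata", "synthetic_v583_pipef.fasta",
                        package = "piptyper", mustWork = TRUE)
    gene <- read_fasta(path, alphabet = "nucleotide")
  }
  stopifnot(length(gene) == 1L, length(vr_aa) == 2L,
            vr_aa[1] >= 1L, vr_aa[1] <= vr_aa[2])
  vr_aa <- as.integer(vr_aa)
  vr_nt <- c(3L * vr_aa[1] - 2L, 3L * vr_aa[2])
  if (vr_nt[2] > nchar(gene))
    stop("variable-region coordinates exceed the reference gene length",
         call. = FALSE)
  protein <- translate_sequence(as.character(gene))
  protein <- sub("\\*$", "", protein)  # drop the terminal stop
  structure(list(gene = gene,
                 protein = setNames(protein, names(gene)),
                 vr_aa = vr_aa, vr_nt = vr_nt),
            class = "reference_anchor")
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat("<reference_anchor> ", names(x$gene), ": gene ", nchar(x$gene),
      " nt, protein ", nchar(x$protein), " aa, variable region aa ",
      x$vr_aa[1], "-", x$vr_aa[2], " (nt ", x$vr_nt[1], "-", x$vr_nt[2],
      ")\n", sep = "")
  invisible(x)
}

#' Extract the PIP variable region from a full-length homolog
#'
#' Globally aligns the query to the anchor reference at the requested level
#' and projects the reference variable-region bounds onto query
#' coordinates.  A boundary that lands on a query gap is snapped inward to
#' the nearest query residue inside the region, so returned coordinates
#' always lie on the query.  Queries whose conserved flanks align to the
#' reference below `min_flank_identity` are rejected as non-homologs; the
#' default floor of 0.50 sits above the ~0.42 identity that global
#' alignment of unrelated DNA reaches under the default scoring, and well
#' below the near-identical flanks of true PIP homologs.
#'
#' @param query full-length gene or protein (length-1 named character)
#' @param anchor a [reference_anchor()]
#' @param level `"nucleotide"` or `"protein"`; guessed from the query when
#'   `NULL`
#' @param min_flank_identity identity floor over the flanking (non-variable)
#'   alignment columns below which the query is not considered a PIP
#'   homolog
#' @return an object of class `variable_region`: `source_id`, `start`,
#'   `end` (1-based inclusive on the query), `residues`, `level`
#' @export
#' @examples
#' anchor <- reference_anchor()
#' vr <- extract_variable_region(anchor$protein, anchor, level = "protein")
#' c(vr$start, vr$end)  # 342 494
extract_variable_region <- function(query, anchor, level = NULL,
                                    min_flank_identity = 0.50) {
  stopifnot(inherits(anchor, "reference_anchor"), length(query) == 1L)
  if (is.null(level)) level <- guess_alphabet(as.character(query))
  level <- match.arg(level, c("nucleotide", "protein"))
  ref <- if (level == "nucleotide") anchor$gene else anchor$protein
  bounds <- if (level == "nucleotide") anchor$vr_nt else anchor$vr_aa
  qid <- names(query) %||% "query"

  aln <- global_align(setNames(as.character(ref), names(ref)),
                      setNames(as.character(query), qid),
                      scoring = scoring_scheme(level))
  ga <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]  # reference
  gb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]  # query
  refpos <- cumsum(ga != "-")
  qpos   <- cumsum(gb != "-")
  in_vr  <- refpos >= bounds[1] & refpos <= bounds[2] & ga != "-"

  # homology guard: identity over the flank columns (reference residues
  # outside the variable region)
  flank <- !in_vr & ga != "-"
  flank_id <- count_matches(ga[flank], gb[flank], aln$alphabet) / sum(flank)
  if (flank_id < min_flank_identity)
    stop("query '", qid, "' is not a PIP homolog (flank identity ",
         sprintf("%.2f", flank_id), " < ", min_flank_identity, ")",
         call. = FALSE)

  keep <- in_vr & gb != "-"
  if (!any(keep))
    stop("query '", qid, "' has no residues aligned inside the variable ",
         "region", call. = FALSE)
  start <- min(qpos[keep]); end <- max(qpos[keep])
  residues <- substr(as.character(query), start, end)
  structure(list(source_id = qid, start = start, end = end,
                 residues = residues, level = level),
            class = "variable_region")
}

#' @export
print.variable_region <- function(x, ...) {
  cat("<variable_region> ", x$source_id, " [", x$start, "-", x$end, "] ",
      x$level, ", ", region_length(x), " residues\n", sep = "")
  invisible(x)
}

#' Length of a variable region
#'
#' @param region a `variable_region`
#' @return `end - start + 1`
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "variable_region"))
  region$end - region$start + 1L
}

#' Extract variable regions from a set of homologs
#'
#' Vectorised convenience around [extract_variable_region()].  When several
#' records share a strain label (e.g. a genome carrying a second YhgE/PIP
#' domain paralog), only the record with the highest flank identity should
#' be kept by the caller; records failing the homology floor are dropped
#' with a warning.
#'
#' @param queries named character vector of full-length genes or proteins
#' @inheritParams extract_variable_region
#' @return named character vector of region sequences with a `coords`
#'   attribute (data.frame: id, start, end, length)
#' @export
extract_variable_regions <- function(queries, anchor, level = NULL,
                                     min_flank_identity = 0.50) {
  regions <- list()
  for (id in names(queries)) {
    vr <- tryCatch(
      extract_variable_region(setNames(queries[[id]], id), anchor,
                              level = level,
                              min_flank_identity = min_flank_identity),
      error = function(e) {
        warning("skipping ", id, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(vr)) regions[[id]] <- vr
  }
  out <- vapply(regions, `[[`, character(1), "residues")
  attr(out, "coords") <- data.frame(
    id = names(regions),
    start = vapply(regions, `[[`, integer(1), "start"),
    end = vapply(regions, `[[`, integer(1), "end"),
    length = vapply(regions, region_length, integer(1)),
    row.names = NULL)
  out
}
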