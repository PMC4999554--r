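#' Clade schemes for PIP variable-region typing
#'
#' A clade scheme bundles an identity threshold (default 0.95 at the
#' nucleotide level), one representative variable-region sequence per
#' clade, the strain roster, and the per-clade phage-susceptibility map for
#' phiVPE25 and phiVFW.
#'
#' @param representatives named character vector of representative
#'   variable-region sequences (names are clade ids); may be `NULL` for a
#'   roster-and-phenotypes-only scheme
#' @param roster named list mapping clade id to a character vector of
#'   strain names; rosters must be disjoint
#' @param susceptibility data.frame with columns `clade`, `phiVPE25`,
#'   `phiVFW`, phenotypes `"sensitive"` or `"resistant"`, covering every
#'   clade
#' @param threshold identity fraction for clade membership
#' @param level `"nucleotide"` or `"protein"`
#' @return an object of class `clade_scheme`
#' @export
clade_scheme <- function(representatives, roster, susceptibility,
                         threshold = 0.95,
                         level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  stopifnot(is.list(roster), length(roster) >= 1,
            threshold > 0, threshold <= 1)
  strains <- unlist(roster, use.names = FALSE)
  if (anyDuplicated(strains))
    stop("clade rosters overlap: ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "),
         call. = FALSE)
  clades <- names(roster)
  stopifnot(is.data.frame(susceptibility),
            all(c("clade", "phiVPE25", "phiVFW") %in% names(susceptibility)))
  susceptibility$clade <- as.character(susceptibility$clade)
  if (!all(clades %in% susceptibility$clade))
    stop("susceptibility map must cover every clade", call. = FALSE)
  phen <- unlist(susceptibility[, c("phiVPE25", "phiVFW")])
  if (!all(phen %in% c("sensitive", "resistant")))
    stop("phenotypes must be 'sensitive' or 'resistant'", call. = FALSE)
  if (!is.null(representatives)) {
    representatives <- setNames(toupper(as.character(representatives)),
                                names(representatives))
    if (!all(names(representatives) %in% clades) ||
        !all(clades %in% names(representatives)))
      stop("representatives must be named by the roster's clade ids",
           call. = FALSE)
  }
  structure(list(threshold = threshold, level = level,
                 representatives = representatives, roster = roster,
                 susceptibility = susceptibility[
                   match(clades, susceptibility$clade), , drop = FALSE]),
            class = "clade_scheme")
}

#' @export
print.clade_scheme <- function(x, ...) {
  cat("<clade_scheme> ", length(x$roster), " clades, threshold ",
      x$threshold, " (", x$level, " level)",
      if (is.null(x$representatives)) ", no representative sequences",
      "\n", sep = "")
  for (cl in names(x$roster))
    cat("  clade ", cl, " (", paste(x$susceptibility[
      x$susceptibility$clade == cl, c("phiVPE25", "phiVFW")], collapse = "/"),
      "): ", paste(x$roster[[cl]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The packaged 19-strain PIP_EF typing scheme
#'
#' Roster and phage phenotypes of the five PIP_EF variable-region clades of
#' E. faecalis (19 strains): clades 1 and 4 are sensitive to both phiVPE25
#' and phiVFW, clades 2 and 3 to phiVPE25 only, clade 5 to phiVFW only.
#' Representative sequences are not packaged (the public gene sequences
#' are not redistributed here); supply them via `representatives` when
#' sequence-based assignment is needed.
#'
#' @param representatives optional named character vector of representative
#'   variable-region sequences, names `"1"` to `"5"`
#' @return a [clade_scheme()]
#' @export
#' @examples
#' pipef_scheme()
pipef_scheme <- function(representatives = NULL) {
  path <- system.file("extdata", "pipef_clades.tsv", package = "piptyper",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  roster <- split(tab$strain, tab$clade)
  susc <- unique(tab[, c("clade", "phiVPE25", "phiVFW")])
  clade_scheme(representatives, roster, susc,
               threshold = 0.95, level = "nucleotide")
}

#' Pairwise identity matrix of variable regions
#'
#' @param regions named character vector of region sequences (uniform
#'   level)
#' @param level alphabet; guessed when `NULL`
#' @param mode identity denominator, see [percent_identity()]
#' @return symmetric numeric matrix with unit diagonal
#' @export
identity_matrix <- function(regions, level = NULL,
                            mode = c("exclude-terminal-gaps",
                                     "all-columns")) {
  mode <- match.arg(mode)
  n <- length(regions)
  if (n < 2) stop("need at least two regions", call. = FALSE)
  levels <- vapply(regions, guess_alphabet, character(1))
  if (is.null(level)) level <- if (any(levels == "protein")) "protein"
                               else "nucleotide"
  if (level == "nucleotide" && any(levels == "protein"))
    stop("regions mix nucleotide and protein sequences", call. = FALSE)
  scoring <- scoring_scheme(level)
  ids <- names(regions) %||% paste0("r", seq_len(n))
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    aln <- global_align(regions[[i]], regions[[j]], scoring = scoring,
                        mode = mode)
    m[i, j] <- m[j, i] <- aln$identity
  }
  m
}

#' Single-linkage clade clustering at an identity threshold
#'
#' Clades are the connected components of the graph whose edges join pairs
#' with identity at or above the threshold (single linkage: chains merge).
#' Clades are numbered by decreasing size, ties broken by the first member
#' in input order, so the labelling is deterministic and invariant to
#' input order.
#'
#' @param m symmetric identity matrix (e.g. from [identity_matrix()])
#' @param threshold identity fraction for joining
#' @return named integer vector: clade number per input sequence
#' @export
#' @examples
#' m <- matrix(c(1, .96, .9, .96, 1, .96, .9, .96, 1), 3,
#'             dimnames = list(c("A","B","C"), c("A","B","C")))
#' cluster_clades(m, 0.95)  # one clade by chaining
cluster_clades <- function(m, threshold = 0.95) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("identity matrix must be symmetric", call. = FALSE)
  n <- nrow(m)
  comp <- integer(n)
  next_comp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    next_comp <- next_comp + 1L
    queue <- s
    comp[s] <- next_comp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(m[v, ] >= threshold & comp == 0L)
      comp[nb] <- next_comp
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  first <- vapply(seq_len(max(comp)), function(k) min(which(comp == k)),
                  integer(1))
  rank <- order(-sizes, first)
  relabel <- integer(max(comp)); relabel[rank] <- seq_along(rank)
  setNames(relabel[comp], rownames(m))
}

#' Medoid representative of each clade
#'
#' The representative of a clade is its medoid: the member with the highest
#' mean identity to its clade-mates (singletons represent themselves).
#'
#' @param regions named character vector of region sequences
#' @param clades named integer vector from [cluster_clades()]
#' @param m optional precomputed identity matrix
#' @return named character vector of representatives, names are clade ids
#' @export
clade_representatives <- function(regions, clades, m = NULL) {
  if (is.null(m)) m <- identity_matrix(regions)
  reps <- character(0)
  for (k in sort(unique(clades))) {
    members <- names(clades)[clades == k]
    if (length(members) == 1L) {
      reps[[as.character(k)]] <- regions[[members]]
    } else {
      sub <- m[members, members, drop = FALSE]
      mean_id <- (rowSums(sub) - 1) / (length(members) - 1)
      best <- members[which.max(mean_id)]
      reps[[as.character(k)]] <- regions[[best]]
    }
  }
  reps
}

#' Assign a query variable region to a clade
#'
#' The query is aligned to every clade representative; it is assigned to
#' the best-identity clade when that identity meets the scheme threshold,
#' and reported `"novel"` otherwise.  An exact tie for the best identity is
#' ambiguous and yields `"novel"` with a warning.
#'
#' @param query region sequence (length-1 character, optionally named) or a
#'   `variable_region`
#' @param scheme a [clade_scheme()] with representative sequences
#' @param mode identity denominator
#' @return an object of class `clade_assignment`: `query_id`, `clade`
#'   (clade id or `"novel"`), `best_identity`, `margin`
#' @export
assign_clade <- function(query, scheme,
                         mode = c("exclude-terminal-gaps", "all-columns")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "clade_scheme"))
  if (is.null(scheme$representatives))
    stop("scheme has no representative sequences", call. = FALSE)
  if (inherits(query, "variable_region")) {
    qid <- query$source_id; qseq <- query$residues
  } else {
    qid <- names(query) %||% "query"; qseq <- as.character(query)
  }
  scoring <- scoring_scheme(scheme$level)
  ids <- vapply(scheme$representatives, function(rep)
    global_align(qseq, rep, scoring = scoring, mode = mode)$identity,
    numeric(1))
  ord <- order(-ids)
  best <- ids[ord[1]]
  second <- if (length(ids) > 1) ids[ord[2]] else -Inf
  margin <- if (is.finite(second)) best - second else NA_real_
  clade <- names(ids)[ord[1]]
  if (best < scheme$threshold) {
    clade <- "novel"
  } else if (is.finite(second) && second == best) {
    warning("query '", qid, "' ties between clades ",
            paste(names(ids)[ids == best], collapse = " and "),
            "; reporting 'novel'", call. = FALSE)
    clade <- "novel"
  }
  structure(list(query_id = qid, clade = clade,
                 best_identity = unname(best),
                 margin = unname(margin)),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat("<clade_assignment> ", x$query_id, " -> clade ", x$clade,
      " (identity ", sprintf("%.3f", x$best_identity), ", margin ",
      sprintf("%.3f", x$margin), ")\n", sep = "")
  invisible(x)
}

#' Predict phage susceptibility from a clade assignment
#'
#' Phenotypes are looked up in the scheme's clade-to-susceptibility map;
#' a `"novel"` clade yields `"unknown"` for both phages.
#'
#' @param assignment a `clade_assignment` (or a clade id string)
#' @param scheme the [clade_scheme()] the assignment was made under
#' @return data.frame with columns `query_id`, `clade`, `phiVPE25`,
#'   `phiVFW`
#' @export
predict_susceptibility <- function(assignment, scheme) {
  stopifnot(inherits(scheme, "clade_scheme"))
  if (inherits(assignment, "clade_assignment")) {
    qid <- assignment$query_id; clade <- assignment$clade
  } else {
    qid <- NA_character_; clade <- as.character(assignment)
  }
  if (identical(clade, "novel")) {
    return(data.frame(query_id = qid, clade = "novel",
                      phiVPE25 = "unknown", phiVFW = "unknown",
                      stringsAsFactors = FALSE))
  }
  row <- scheme$susceptibility[scheme$susceptibility$clade == clade, ,
                               drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown clade id: ", clade, call. = FALSE)
  data.frame(query_id = qid, clade = clade,
             phiVPE25 = row$phiVPE25, phiVFW = row$phiVFW,
             stringsAsFactors = FALSE)
}
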