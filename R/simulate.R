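#' Simulation configuration
#'
#' Parameters for the synthetic-data generator.  Defaults mirror the study
#' system: a PIP-like gene with the reference geometry (1023-nt 5' flank,
#' 459-nt variable region, 1185-nt 3' flank), five clades with the
#' 10/1/2/2/4 strain roster sizes, within-clade variable-region identity
#' above and between-clade identity below the 0.95 typing threshold,
#' 250-nt amplicon reads, and a loss-of-function mutation spectrum (stop
#' SNPs, missense SNPs, small indels of 1-10 nt, and a 1300-nt IS-like
#' cassette).
#'
#' @param seed integer seed; every generator output is a pure function of
#'   the config, so equal configs give byte-identical output
#' @param n_clades number of clades
#' @param members_per_clade integer vector (recycled) of clade sizes
#' @param within_identity,between_identity variable-region nucleotide
#'   identity targets inside and across clades (between must be below
#'   within)
#' @param flank5_length,vr_length,flank3_length gene geometry in nt
#' @param flank_identity pairwise identity target for the conserved flanks
#' @param read_length amplicon read length in nt
#' @param substitution_rate,indel_rate per-base sequencing error rates for
#'   simulated reads
#' @param spectrum mutation-spectrum weights, named
#'   `nonsense`, `missense`, `small_indel`, `is_insertion`
#' @param is_length IS-like cassette length in nt
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed,
                       n_clades = 5L,
                       members_per_clade = c(10L, 1L, 2L, 2L, 4L),
                       within_identity = 0.98,
                       between_identity = 0.80,
                       flank5_length = 1023L,
                       vr_length = 459L,
                       flank3_length = 1185L,
                       flank_identity = 0.998,
                       read_length = 250L,
                       substitution_rate = 0.01,
                       indel_rate = 0,
                       spectrum = c(nonsense = 0.25, missense = 0.05,
                                    small_indel = 0.45,
                                    is_insertion = 0.25),
                       is_length = 1300L) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_clades >= 1L, all(members_per_clade >= 1L),
            within_identity > 0, within_identity <= 1,
            between_identity > 0, between_identity <= 1,
            flank_identity > 0, flank_identity <= 1,
            read_length >= 1L, substitution_rate >= 0, indel_rate >= 0,
            is_length >= 1L)
  if (between_identity >= within_identity)
    stop("infeasible identity targets: between-clade identity must be ",
         "below within-clade identity", call. = FALSE)
  if (read_length > vr_length)
    stop("read length exceeds the variable-region length", call. = FALSE)
  stopifnot(all(c("nonsense", "missense", "small_indel", "is_insertion")
                %in% names(spectrum)),
            all(spectrum >= 0), sum(spectrum) > 0)
  structure(list(seed = as.integer(seed), n_clades = as.integer(n_clades),
                 members_per_clade =
                   rep_len(as.integer(members_per_clade), n_clades),
                 within_identity = within_identity,
                 between_identity = between_identity,
                 flank5_length = as.integer(flank5_length),
                 vr_length = as.integer(vr_length),
                 flank3_length = as.integer(flank3_length),
                 flank_identity = flank_identity,
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 spectrum = spectrum / sum(spectrum),
                 is_length = as.integer(is_length)),
            class = "sim_config")
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# substitute each site independently with probability `rate`, always to a
# different base
mutate_sites <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    idx <- match(ch[hit], DNA_BASES)
    ch[hit] <- DNA_BASES[1L + (idx - 1L +
                               sample(1:3, length(hit), replace = TRUE)) %% 4L]
  }
  paste(ch, collapse = "")
}

# per-ancestor divergence d such that two sequences independently mutated
# at rate d from a common ancestor differ at a fraction m of sites
# (both-mutated sites still coincide with probability 1/3)
solve_divergence <- function(m) {
  if (m <= 0) return(0)
  if (m >= 0.74)
    stop("identity target too low to realise by substitution", call. = FALSE)
  stats::uniroot(function(d) 2 * d * (1 - d) + (2 / 3) * d^2 - m,
                 c(0, 0.749), tol = 1e-10)$root
}

# fraction of equal sites between equal-length strings
hamming_identity <- function(x, y) {
  mean(utf8ToInt(x) == utf8ToInt(y))
}

#' Generate a clade-structured gene panel with known truth
#'
#' Builds one random ancestral gene, derives one ancestor per clade by
#' mutating the variable region to the between-clade identity target, then
#' derives each member by mutating its clade ancestor's variable region to
#' the within-clade target; flanks stay near-identical across all members.
#' Realised mean identities are verified to be within two percentage
#' points of the targets, resampling otherwise.  The returned scheme uses
#' each clade's medoid variable region as representative and assigns
#' phage-susceptibility patterns cyclically from the packaged five-clade
#' map.
#'
#' @param cfg a [sim_config()]
#' @return list with elements `sequences` (full-length genes),
#'   `regions` (variable regions), `scheme` (a [clade_scheme()] with
#'   representatives), `truth` (data.frame `id`, `clade`), `config`
#' @export
generate_clade_scheme <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  d_b <- solve_divergence(1 - cfg$between_identity)
  d_w <- solve_divergence(1 - cfg$within_identity)
  d_f <- solve_divergence(1 - cfg$flank_identity)
  tol <- 0.02

  for (attempt in seq_len(25L)) {
    flank5 <- random_dna(cfg$flank5_length)
    flank3 <- random_dna(cfg$flank3_length)
    root_vr <- random_dna(cfg$vr_length)
    clade_vr <- vapply(seq_len(cfg$n_clades),
                       function(i) mutate_sites(root_vr, d_b), character(1))
    ids <- character(0); clade_of <- integer(0)
    vr <- character(0); genes <- character(0)
    for (cl in seq_len(cfg$n_clades)) {
      for (mem in seq_len(cfg$members_per_clade[cl])) {
        id <- sprintf("sim_c%d_m%d", cl, mem)
        v <- mutate_sites(clade_vr[cl], d_w)
        g <- paste0(mutate_sites(flank5, d_f), v, mutate_sites(flank3, d_f))
        ids <- c(ids, id); clade_of <- c(clade_of, cl)
        vr <- c(vr, v); genes <- c(genes, g)
      }
    }
    names(vr) <- ids; names(genes) <- ids

    # calibration: realised identities near targets (no indels, so
    # Hamming identity equals alignment identity)
    n <- length(ids)
    within_ids <- c(); between_ids <- c()
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      h <- hamming_identity(vr[[i]], vr[[j]])
      if (clade_of[i] == clade_of[j]) within_ids <- c(within_ids, h)
      else between_ids <- c(between_ids, h)
    }
    ok_within <- length(within_ids) == 0 ||
      abs(mean(within_ids) - cfg$within_identity) <= tol
    ok_between <- cfg$n_clades == 1L ||
      abs(mean(between_ids) - cfg$between_identity) <= tol
    if (ok_within && ok_between) break
    if (attempt == 25L)
      stop("could not calibrate identities to targets", call. = FALSE)
  }

  truth <- data.frame(id = ids, clade = clade_of, stringsAsFactors = FALSE)
  m <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) hamming_identity(vr[[i]], vr[[j]])))
  dimnames(m) <- list(ids, ids)
  reps <- clade_representatives(vr, setNames(clade_of, ids), m = m)

  # susceptibility patterns recycled from the packaged five-clade map
  patterns <- data.frame(
    phiVPE25 = c("sensitive", "sensitive", "sensitive", "sensitive",
                 "resistant"),
    phiVFW = c("sensitive", "resistant", "resistant", "sensitive",
               "sensitive"),
    stringsAsFactors = FALSE)
  pat <- patterns[((seq_len(cfg$n_clades) - 1L) %% nrow(patterns)) + 1L, ]
  susc <- data.frame(clade = as.character(seq_len(cfg$n_clades)),
                     phiVPE25 = pat$phiVPE25, phiVFW = pat$phiVFW,
                     stringsAsFactors = FALSE)
  roster <- split(ids, clade_of)
  names(roster) <- as.character(seq_len(cfg$n_clades))
  scheme <- clade_scheme(reps, roster, susc, threshold = 0.95,
                         level = "nucleotide")
  list(sequences = seq_records(genes, alphabet = "nucleotide"),
       regions = seq_records(vr, alphabet = "nucleotide"),
       scheme = scheme, truth = truth, config = cfg)
}

#' Simulate variable-region amplicon reads from a clade mixture
#'
#' Each read draws its source clade from the mixture, a uniform window of
#' `read_length` nt from that clade's representative variable region and a
#' random orientation, then acquires substitution (and optionally
#' single-base indel) errors at the configured rates.  Qualities are
#' uniform placeholders (Q40).
#'
#' @param scheme a [clade_scheme()] with nucleotide representatives
#' @param mixture named numeric vector of clade weights (sums to 1);
#'   `NULL` for a uniform mixture
#' @param n_reads number of reads
#' @param cfg a [sim_config()] (seed and error rates are taken from it)
#' @return list with elements `reads` (named character with a
#'   `qualities` attribute) and `truth` (data.frame `read_id`, `clade`,
#'   `start`, `orientation`)
#' @export
simulate_amplicon_reads <- function(scheme, mixture = NULL, n_reads, cfg) {
  stopifnot(inherits(scheme, "clade_scheme"), inherits(cfg, "sim_config"),
            n_reads >= 1L)
  if (is.null(scheme$representatives))
    stop("scheme has no representative sequences", call. = FALSE)
  reps <- scheme$representatives
  if (is.null(mixture))
    mixture <- setNames(rep(1 / length(reps), length(reps)), names(reps))
  if (!all(names(mixture) %in% names(reps)))
    stop("mixture names must be scheme clade ids", call. = FALSE)
  if (abs(sum(mixture) - 1) > 1e-6)
    stop("mixture weights must sum to 1", call. = FALSE)
  if (any(nchar(reps) < cfg$read_length))
    stop("read length exceeds a representative region length",
         call. = FALSE)
  set.seed(cfg$seed)

  clades <- sample(names(mixture), n_reads, replace = TRUE, prob = mixture)
  reads <- character(n_reads)
  starts <- integer(n_reads)
  orient <- sample(c("+", "-"), n_reads, replace = TRUE)
  for (k in seq_len(n_reads)) {
    rep_seq <- reps[[clades[k]]]
    s <- sample.int(nchar(rep_seq) - cfg$read_length + 1L, 1L)
    r <- substr(rep_seq, s, s + cfg$read_length - 1L)
    r <- mutate_sites(r, cfg$substitution_rate)
    if (cfg$indel_rate > 0) {
      ch <- strsplit(r, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(ch)) < cfg$indel_rate)
      for (i in rev(hit)) {
        if (stats::runif(1) < 0.5) ch <- ch[-i]
        else ch <- append(ch, sample(DNA_BASES, 1L), after = i)
      }
      r <- paste(ch, collapse = "")
    }
    if (orient[k] == "-") r <- reverse_complement(r)
    reads[k] <- r
    starts[k] <- s
  }
  ids <- sprintf("read_%d", seq_len(n_reads))
  out <- seq_records(reads, ids = ids, alphabet = "nucleotide")
  attr(out, "qualities") <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  list(reads = out,
       truth = data.frame(read_id = ids, clade = clades, start = starts,
                          orientation = orient, stringsAsFactors = FALSE))
}

# enumerate (pos, alt) single-base substitutions that create a premature
# stop codon in an ORF
premature_stop_sites <- function(ref) {
  stops <- c("TAA", "TAG", "TGA")
  n_codons <- nchar(ref) %/% 3L
  sites <- list()
  for (codon in seq_len(n_codons - 1L)) {
    cstart <- 3L * (codon - 1L) + 1L
    cd <- substr(ref, cstart, cstart + 2L)
    if (translate_sequence(cd) == "*") next
    for (p in 1:3) for (b in DNA_BASES) {
      if (substr(cd, p, p) == b) next
      alt <- cd
      substr(alt, p, p) <- b
      if (alt %in% stops)
        sites[[length(sites) + 1L]] <- c(pos = cstart + p - 1L,
                                         alt = b)
    }
  }
  sites
}

#' Simulate phage-resistant isolate gene sequences
#'
#' Each isolate carries exactly one planted lesion drawn from the
#' mutation-spectrum weights: a premature-stop SNP, a missense SNP, a
#' small indel (1-10 nt) or an IS-like cassette insertion at a uniform
#' position.  Planted indels are recorded left-aligned (the caller's
#' convention) so truth and calls are directly comparable.  The truth
#' phenotype follows the loss-of-function rule: nonsense, frameshift and
#' IS lesions are resistant; in-frame deletions only when they cut the
#' variable region.
#'
#' @param reference intact ORF to mutagenise (length-1 named character);
#'   defaults to the packaged synthetic reference gene
#' @param n_isolates number of isolates
#' @param cfg a [sim_config()]
#' @param anchor a [reference_anchor()] matching `reference`, used for the
#'   truth phenotype of in-frame deletions
#' @return list with elements `sequences` (named character) and `truth`
#'   (data.frame `isolate_id`, `lesion`, `pos`, `ref`, `alt`,
#'   `phenotype`)
#' @export
simulate_resistant_isolates <- function(reference = NULL, n_isolates, cfg,
                                        anchor = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_isolates >= 1L)
  if (is.null(anchor) && is.null(reference)) anchor <- reference_anchor()
  if (is.null(reference)) reference <- anchor$gene
  ref <- toupper(as.character(reference))
  if (nchar(ref) %% 3L != 0L)
    stop("reference must be an intact ORF (length divisible by 3)",
         call. = FALSE)
  prot <- translate_sequence(ref)
  if (grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
    stop("reference ORF contains an internal stop codon", call. = FALSE)
  vr <- if (!is.null(anchor)) anchor$vr_nt
        else if (nchar(ref) >= 1482L) c(1024L, 1482L) else c(NA, NA)
  set.seed(cfg$seed)

  stop_sites <- premature_stop_sites(ref)
  len <- nchar(ref)
  types <- sample(names(cfg$spectrum), n_isolates, replace = TRUE,
                  prob = cfg$spectrum)
  seqs <- character(n_isolates)
  truth <- vector("list", n_isolates)
  for (k in seq_len(n_isolates)) {
    type <- types[k]
    if (type == "nonsense") {
      site <- stop_sites[[sample.int(length(stop_sites), 1L)]]
      pos <- as.integer(site[["pos"]]); alt <- site[["alt"]]
      rec <- list(lesion = "SNP", pos = pos,
                  ref = substr(ref, pos, pos), alt = alt,
                  phenotype = "resistant")
    } else if (type == "missense") {
      repeat {
        pos <- sample.int(len - 3L, 1L)  # keep the terminal stop intact
        alt <- sample(setdiff(DNA_BASES, substr(ref, pos, pos)), 1L)
        codon <- ceiling(pos / 3)
        cstart <- 3L * (codon - 1L) + 1L
        mut_codon <- substr(ref, cstart, cstart + 2L)
        substr(mut_codon, pos - cstart + 1L, pos - cstart + 1L) <- alt
        aa_ref <- translate_sequence(substr(ref, cstart, cstart + 2L))
        aa_alt <- translate_sequence(mut_codon)
        if (aa_alt != aa_ref && aa_alt != "*") break
      }
      rec <- list(lesion = "SNP", pos = pos,
                  ref = substr(ref, pos, pos), alt = alt,
                  phenotype = "sensitive")
    } else if (type == "small_indel") {
      L <- sample.int(10L, 1L)
      if (stats::runif(1) < 0.5) {  # deletion
        pos <- sample.int(len - L + 1L, 1L)
        norm <- left_align_indel(ref, "deletion", pos,
                                 substr(ref, pos, pos + L - 1L))
        phen <- if (L %% 3L != 0L) "resistant"
                else if (!is.na(vr[1]) &&
                         norm$pos + L - 1L >= vr[1] && norm$pos <= vr[2])
                  "resistant" else "sensitive"
        rec <- list(lesion = "deletion", pos = norm$pos,
                    ref = norm$allele, alt = "", phenotype = phen)
      } else {                      # insertion
        pos <- sample.int(len, 1L) - 1L  # after this base (0 = before 1)
        ins <- random_dna(L)
        norm <- left_align_indel(ref, "insertion", pos, ins)
        phen <- if (L %% 3L != 0L) "resistant" else "sensitive"
        rec <- list(lesion = "insertion", pos = norm$pos, ref = "",
                    alt = norm$allele, phenotype = phen)
      }
    } else {                        # is_insertion
      pos <- sample.int(len, 1L) - 1L
      cassette <- random_dna(cfg$is_length)
      norm <- left_align_indel(ref, "insertion", pos, cassette)
      rec <- list(lesion = "IS-insertion", pos = norm$pos, ref = "",
                  alt = norm$allele, phenotype = "resistant")
    }
    seqs[k] <- apply_variant(ref,
                             if (rec$lesion %in%
                                 c("insertion", "IS-insertion"))
                               "insertion" else rec$lesion,
                             rec$pos, rec$ref, rec$alt)
    truth[[k]] <- rec
  }
  ids <- sprintf("isolate_%d", seq_len(n_isolates))
  list(sequences = seq_records(seqs, ids = ids, alphabet = "nucleotide"),
       truth = data.frame(
         isolate_id = ids,
         lesion = vapply(truth, `[[`, character(1), "lesion"),
         pos = vapply(truth, function(x) as.integer(x$pos), integer(1)),
         ref = vapply(truth, `[[`, character(1), "ref"),
         alt = vapply(truth, `[[`, character(1), "alt"),
         phenotype = vapply(truth, `[[`, character(1), "phenotype"),
         stringsAsFactors = FALSE))
}
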