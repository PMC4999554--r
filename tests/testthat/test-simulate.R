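test_that("infeasible identity targets are a config error", {
  expect_error(sim_config(seed = 1, within_identity = 0.8,
                          between_identity = 0.9), "infeasible")
  expect_error(sim_config(seed = 1, read_length = 500), "read length")
})

test_that("a single-clade panel stays above the within-identity target", {
  sim <- generate_clade_scheme(sim_config(seed = 6, n_clades = 1,
                                          members_per_clade = 6))
  m <- identity_matrix(sim$regions)
  expect_true(all(m[upper.tri(m)] >= 0.95))
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 19, members_per_clade = 3)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(generate_clade_scheme(cfg)$sequences, f1)
  write_fasta(generate_clade_scheme(cfg)$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))

  sim <- generate_clade_scheme(cfg)
  r1 <- tempfile(); r2 <- tempfile()
  write_fastq(simulate_amplicon_reads(sim$scheme, NULL, 30, cfg)$reads, r1)
  write_fastq(simulate_amplicon_reads(sim$scheme, NULL, 30, cfg)$reads, r2)
  expect_identical(readLines(r1), readLines(r2))

  i1 <- simulate_resistant_isolates(n_isolates = 10, cfg = cfg)
  i2 <- simulate_resistant_isolates(n_isolates = 10, cfg = cfg)
  expect_identical(i1$sequences, i2$sequences)
  expect_identical(i1$truth, i2$truth)
})

test_that("realised identities are calibrated to the targets", {
  within <- c(); between <- c()
  for (seed in 1:10) {
    sim <- generate_clade_scheme(sim_config(seed = seed,
                                            members_per_clade = 3))
    m <- identity_matrix(sim$regions)
    cl <- sim$truth$clade
    for (i in seq_len(nrow(m) - 1)) for (j in seq(i + 1, nrow(m))) {
      if (cl[i] == cl[j]) within <- c(within, m[i, j])
      else between <- c(between, m[i, j])
    }
  }
  expect_lt(abs(mean(within) - 0.98), 0.02)
  expect_lt(abs(mean(between) - 0.80), 0.02)
})

test_that("zero-error reads from one clade all classify to that clade", {
  sim <- small_panel(seed = 50, members = 4)
  cfg0 <- sim_config(seed = 50, members_per_clade = 4,
                     substitution_rate = 0)
  rd <- simulate_amplicon_reads(sim$scheme, c("3" = 1), 50, cfg0)
  asn <- classify_reads(rd$reads, sim$scheme)
  expect_true(all(asn$clade == "3"))
  expect_true(all(asn$identity == 1))
})

test_that("planted lesions are recovered by the caller (round trip)", {
  anchor <- reference_anchor()
  cfg <- sim_config(seed = 23)
  iso <- simulate_resistant_isolates(n_isolates = 60, cfg = cfg,
                                     anchor = anchor)
  tp <- 0L
  for (k in seq_len(60)) {
    calls <- call_variants(iso$sequences[k], anchor$gene)
    expect_identical(nrow(calls), 1L, info = iso$truth$isolate_id[k])
    truth <- iso$truth[k, ]
    type_map <- c(SNP = "SNP", deletion = "deletion",
                  insertion = "insertion", `IS-insertion` = "IS-insertion")
    expect_identical(calls$type, unname(type_map[truth$lesion]))
    expect_identical(calls$pos, truth$pos)
    expect_identical(calls$ref, truth$ref)
    expect_identical(calls$alt, truth$alt)
    tp <- tp + 1L
  }
  expect_identical(tp, 60L)  # precision = recall = 1 on this panel
})

test_that("planted phenotypes are recovered end to end", {
  anchor <- reference_anchor()
  cfg <- sim_config(seed = 71)
  iso <- simulate_resistant_isolates(n_isolates = 40, cfg = cfg,
                                     anchor = anchor)
  for (k in seq_len(40)) {
    geno <- classify_resistance(
      annotate_consequence(call_variants(iso$sequences[k], anchor$gene),
                           anchor$gene),
      anchor, iso$truth$isolate_id[k])
    expect_identical(geno$phenotype, iso$truth$phenotype[k],
                     info = iso$truth$isolate_id[k])
  }
})

test_that("all-nonsense spectra produce only premature stops at planted codons", {
  anchor <- reference_anchor()
  cfg <- sim_config(seed = 31,
                    spectrum = c(nonsense = 1, missense = 0,
                                 small_indel = 0, is_insertion = 0))
  iso <- simulate_resistant_isolates(n_isolates = 25, cfg = cfg,
                                     anchor = anchor)
  for (k in seq_len(25)) {
    calls <- annotate_consequence(
      call_variants(iso$sequences[k], anchor$gene), anchor$gene)
    expect_identical(calls$consequence, "nonsense")
    expect_identical(calls$codon, as.integer(ceiling(iso$truth$pos[k] / 3)))
  }
})

test_that("in-frame deletions outside the region are classified sensitive", {
  anchor <- reference_anchor()
  g <- anchor$gene[[1]]
  # plant 3-nt in-frame deletions well outside nt 1024-1482
  for (pos in c(120L, 2100L)) {
    iso <- paste0(substr(g, 1, pos - 1), substr(g, pos + 3, nchar(g)))
    geno <- classify_resistance(
      annotate_consequence(call_variants(c(i = iso), anchor$gene),
                           anchor$gene), anchor)
    expect_identical(geno$phenotype, "sensitive")
  }
})

test_that("mixture weights must be valid", {
  sim <- small_panel(seed = 2, members = 2)
  cfg <- sim_config(seed = 2, members_per_clade = 2)
  expect_error(simulate_amplicon_reads(sim$scheme, c("1" = 0.5), 10, cfg),
               "sum to 1")
  expect_error(simulate_amplicon_reads(sim$scheme, c(zz = 1), 10, cfg),
               "clade ids")
})
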