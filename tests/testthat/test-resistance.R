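anchor <- reference_anchor()
ref <- anchor$gene

test_that("an identical isolate yields no variant calls", {
  calls <- call_variants(c(iso = ref[[1]]), ref)
  expect_identical(nrow(calls), 0L)
  geno <- classify_resistance(annotate_consequence(calls, ref), anchor,
                              "iso")
  expect_identical(geno$phenotype, "sensitive")
})

test_that("a planted SNP is called at its exact position", {
  g <- ref[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), substr(g, 300, 300))[1]
  iso <- substitute_at(g, 300, alt)
  calls <- call_variants(c(iso = iso), ref)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$type, "SNP")
  expect_identical(calls$pos, 300L)
  expect_identical(calls$ref, substr(g, 300, 300))
  expect_identical(calls$alt, alt)
  expect_false(calls$in_variable_region)
})

test_that("a planted mutation spectrum is recovered exactly", {
  g <- ref[[1]]
  iso <- g
  # right-to-left so earlier coordinates stay valid:
  # 1300-nt insertion after nt 2000, 4-nt deletion at 1600-1603,
  # SNPs at 600 and 1100
  set.seed(17)
  cassette <- random_dna_str(1300)
  iso <- paste0(substr(iso, 1, 2000), cassette,
                substr(iso, 2001, nchar(iso)))
  iso <- paste0(substr(iso, 1, 1599), substr(iso, 1604, nchar(iso)))
  iso <- substitute_at(iso, 1100,
                       setdiff(c("A","C","G","T"),
                               substr(iso, 1100, 1100))[1])
  iso <- substitute_at(iso, 600,
                       setdiff(c("A","C","G","T"),
                               substr(iso, 600, 600))[1])
  calls <- call_variants(c(iso = iso), ref)
  expect_identical(calls$type, c("SNP", "SNP", "deletion", "IS-insertion"))
  expect_identical(calls$pos[1:2], c(600L, 1100L))
  # indels are left-aligned; compare against the canonical representation
  del <- piptyper:::left_align_indel(g, "deletion", 1600L,
                          substr(g, 1600, 1603))
  expect_identical(calls$pos[3], del$pos)
  expect_identical(calls$ref[3], del$allele)
  ins <- piptyper:::left_align_indel(g, "insertion", 2000L, cassette)
  expect_identical(calls$pos[4], ins$pos)
  expect_identical(calls$alt[4], ins$allele)
  expect_true(calls$in_variable_region[2])   # nt 1100 is inside 1024-1482
  expect_false(calls$in_variable_region[1])
})

test_that("indels are reported at their leftmost homopolymer position", {
  g <- paste0("ATG", "CCC", "AAAAAA", "GGG", "TAA")
  # delete one A from the run: every placement is equivalent; the call
  # must be at the first A (position 7)
  iso <- paste0("ATG", "CCC", "AAAAA", "GGG", "TAA")
  calls <- call_variants(c(i = iso), c(r = g))
  expect_identical(calls$type, "deletion")
  expect_identical(calls$pos, 7L)
  expect_identical(calls$ref, "A")
})

test_that("unrelated sequences are not comparable", {
  set.seed(23)
  expect_error(call_variants(c(x = random_dna_str(2667)), ref),
               "not comparable")
})

test_that("SNP consequences follow the genetic code", {
  # build an ORF where codon 100 is CAA (Gln); C->T makes TAA (stop)
  set.seed(31)
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA","TAG","TGA"))
  body <- sample(setdiff(sense, "ATG"), 887, replace = TRUE)
  body[99] <- "CAA"  # codon 100 of the ORF
  orf <- paste(c("ATG", body, "TAA"), collapse = "")
  stopifnot(nchar(orf) == 2667)

  iso <- substitute_at(orf, 298, "T")  # codon 100, first base
  calls <- annotate_consequence(call_variants(c(i = iso), c(r = orf)),
                                c(r = orf))
  expect_identical(calls$consequence, "nonsense")
  expect_identical(calls$codon, 100L)
  expect_identical(calls$truncated_length, 99L)

  # synonymous: CAA -> CAG (both Gln)
  iso2 <- substitute_at(orf, 300, "G")
  calls2 <- annotate_consequence(call_variants(c(i = iso2), c(r = orf)),
                                 c(r = orf))
  expect_identical(calls2$consequence, "synonymous")

  # missense: CAA -> CTA (Leu)
  iso3 <- substitute_at(orf, 299, "T")
  calls3 <- annotate_consequence(call_variants(c(i = iso3), c(r = orf)),
                                 c(r = orf))
  expect_identical(calls3$consequence, "missense")
})

test_that("indel consequences follow net length modulo three", {
  g <- ref[[1]]
  del1 <- paste0(substr(g, 1, 899), substr(g, 901, nchar(g)))
  a1 <- annotate_consequence(call_variants(c(i = del1), ref), ref)
  expect_identical(a1$consequence, "frameshift")
  expect_false(is.na(a1$truncated_length))

  del3 <- paste0(substr(g, 1, 899), substr(g, 903, nchar(g)))
  a3 <- annotate_consequence(call_variants(c(i = del3), ref), ref)
  expect_identical(a3$consequence, "in-frame-indel")
  expect_true(is.na(a3$truncated_length))
})

test_that("resistance classification applies the loss-of-function rule", {
  g <- ref[[1]]
  # IS-like cassette in the 5' region -> resistant
  set.seed(41)
  iso_is <- paste0(substr(g, 1, 150), random_dna_str(1300),
                   substr(g, 151, nchar(g)))
  geno <- classify_resistance(
    annotate_consequence(call_variants(c(i = iso_is), ref), ref),
    anchor, "iso_is")
  expect_identical(geno$phenotype, "resistant")
  expect_match(geno$reason, "IS insertion")

  # in-frame deletion inside the variable region -> resistant
  iso_vr <- paste0(substr(g, 1, 1100), substr(g, 1104, nchar(g)))
  geno_vr <- classify_resistance(
    annotate_consequence(call_variants(c(i = iso_vr), ref), ref),
    anchor, "iso_vr")
  expect_identical(geno_vr$phenotype, "resistant")
  expect_match(geno_vr$reason, "variable region")

  # in-frame deletion outside the region -> sensitive
  iso_out <- paste0(substr(g, 1, 300), substr(g, 304, nchar(g)))
  geno_out <- classify_resistance(
    annotate_consequence(call_variants(c(i = iso_out), ref), ref),
    anchor, "iso_out")
  expect_identical(geno_out$phenotype, "sensitive")
})

test_that("missense-only genotypes are sensitive but flagged", {
  g <- ref[[1]]
  # codon 2 of the synthetic reference; force a missense change
  codon2 <- substr(g, 4, 6)
  alt <- NULL
  for (b in c("A","C","G","T")) {
    cand <- paste0(b, substr(codon2, 2, 3))
    if (b != substr(codon2, 1, 1) &&
        !translate_sequence(cand) %in% c(translate_sequence(codon2), "*")) {
      alt <- b; break
    }
  }
  iso <- substitute_at(g, 4, alt)
  geno <- classify_resistance(
    annotate_consequence(call_variants(c(i = iso), ref), ref),
    anchor, "iso")
  expect_identical(geno$phenotype, "sensitive")
  expect_match(geno$reason, "flagged for review")
})

test_that("adding a loss-of-function call never flips resistant to sensitive", {
  g <- ref[[1]]
  iso <- substitute_at(g, 4, "T")  # some benign-ish SNP
  calls <- annotate_consequence(call_variants(c(i = iso), ref), ref)
  base_pheno <- classify_resistance(calls, anchor)$phenotype
  # append a frameshift call by hand and reclassify
  extra <- calls[0, ]
  extra[1, ] <- list("deletion", 50L, substr(g, 50, 50), "", FALSE,
                     "frameshift", 17L, 60L)
  more <- rbind(calls, extra)
  class(more) <- c("variant_calls", "data.frame")
  expect_identical(classify_resistance(more, anchor)$phenotype, "resistant")
  expect_true(base_pheno %in% c("sensitive", "resistant"))
})
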