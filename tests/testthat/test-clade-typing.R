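test_that("identity matrix matches per-pair realignment and is symmetric", {
  set.seed(21)
  regs <- setNames(vapply(1:4, function(i) random_dna_str(60), ""),
                   paste0("r", 1:4))
  m <- identity_matrix(regs)
  expect_identical(diag(m), setNames(rep(1, 4), names(regs)))
  expect_identical(m, t(m))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m[i, j], global_align(regs[[i]], regs[[j]])$identity)
})

test_that("two identical regions give off-diagonal identity 1", {
  m <- identity_matrix(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_identical(m["a", "b"], 1)
})

test_that("a single substitution in 100 nt gives 0.99 on all columns", {
  a <- random_dna_str(100)
  b <- substitute_at(a, 50, setdiff(c("A","C","G","T"),
                                    substr(a, 50, 50))[1])
  aln <- global_align(a, b)
  expect_equal(percent_identity(aln, "all-columns"), 0.99)
})

test_that("single linkage chains through intermediate members", {
  m <- matrix(c(1, .96, .90,
                .96, 1, .96,
                .90, .96, 1), 3, byrow = TRUE,
              dimnames = list(c("A","B","C"), c("A","B","C")))
  cl <- cluster_clades(m, 0.95)
  expect_identical(unname(cl), rep(1L, 3))
})

test_that("clustering recovers a planted five-clade partition exactly", {
  for (seed in c(42, 7, 2026)) {
    sim <- small_panel(seed = seed, members = 5)
    m <- identity_matrix(sim$regions)
    cl <- cluster_clades(m, 0.95)
    # same partition as the planted truth (labels may permute)
    expect_identical(length(unique(cl)), 5L)
    tab <- table(cl, sim$truth$clade)
    expect_true(all(rowSums(tab > 0) == 1), info = paste("seed", seed))
  }
})

test_that("clustering is invariant to input order and monotone in threshold", {
  sim <- small_panel(seed = 13, members = 3)
  m <- identity_matrix(sim$regions)
  cl <- cluster_clades(m, 0.95)
  set.seed(1)
  perm <- sample(nrow(m))
  cl_perm <- cluster_clades(m[perm, perm], 0.95)
  # same partition (labels may differ when clades tie on size):
  # any two members are clade-mates in one clustering iff in the other
  for (i in seq_len(nrow(m) - 1)) for (j in seq(i + 1, nrow(m))) {
    a <- rownames(m)[i]; b <- rownames(m)[j]
    expect_identical(cl[[a]] == cl[[b]], cl_perm[[a]] == cl_perm[[b]])
  }

  # raising the threshold only ever splits clades, never merges them
  for (th in c(0.90, 0.95, 0.99)) {
    lo <- cluster_clades(m, th)
    hi <- cluster_clades(m, th + 0.005)
    # each high-threshold clade must sit inside one low-threshold clade
    for (k in unique(hi)) {
      members <- names(hi)[hi == k]
      expect_identical(length(unique(lo[members])), 1L)
    }
  }
})

test_that("assignment returns the representative's own clade at identity 1", {
  sim <- small_panel(seed = 31, members = 4)
  for (cl in names(sim$scheme$representatives)) {
    asn <- assign_clade(sim$scheme$representatives[cl], sim$scheme)
    expect_identical(asn$clade, cl)
    expect_identical(asn$best_identity, 1)
  }
})

test_that("a lightly mutated clade member is assigned to its clade", {
  sim <- small_panel(seed = 8, members = 4)
  set.seed(1)
  q <- sim$scheme$representatives[["2"]]
  for (p in sample(nchar(q), round(0.01 * nchar(q))))
    q <- substitute_at(q, p, sample(setdiff(c("A","C","G","T"),
                                            substr(q, p, p)), 1))
  asn <- assign_clade(c(query = q), sim$scheme)
  expect_identical(asn$clade, "2")
  expect_gte(asn$best_identity, 0.95)
  expect_gt(asn$margin, 0)
})

test_that("below-threshold queries are reported novel with unknown phenotype", {
  sim <- small_panel(seed = 77, members = 3)
  set.seed(2)
  asn <- assign_clade(c(rand = random_dna_str(459)), sim$scheme)
  expect_identical(asn$clade, "novel")
  pred <- predict_susceptibility(asn, sim$scheme)
  expect_identical(pred$phiVPE25, "unknown")
  expect_identical(pred$phiVFW, "unknown")
})

test_that("exact representative ties are ambiguous and reported novel", {
  reps <- c("1" = "ACGTACGTACGT", "2" = "ACGTACGTACGT")
  scheme <- clade_scheme(reps,
                         list("1" = "s1", "2" = "s2"),
                         data.frame(clade = c("1", "2"),
                                    phiVPE25 = "sensitive",
                                    phiVFW = "sensitive"))
  expect_warning(asn <- assign_clade("ACGTACGTACGT", scheme), "ties")
  expect_identical(asn$clade, "novel")
})

test_that("the packaged scheme encodes the printed roster and phenotypes", {
  sch <- pipef_scheme()
  expect_identical(length(sch$roster), 5L)
  expect_identical(sum(lengths(sch$roster)), 19L)
  expect_identical(sch$threshold, 0.95)
  expect_true("V583" %in% sch$roster[["4"]])
  expect_true("E1Sol" %in% sch$roster[["5"]])
  # V583's clade is sensitive to both phages, E1Sol's resists phiVPE25 only
  p4 <- predict_susceptibility("4", sch)
  expect_identical(c(p4$phiVPE25, p4$phiVFW), c("sensitive", "sensitive"))
  p5 <- predict_susceptibility("5", sch)
  expect_identical(c(p5$phiVPE25, p5$phiVFW), c("resistant", "sensitive"))
  expect_error(predict_susceptibility("9", sch), "unknown clade")
})

test_that("scheme invariants are enforced", {
  expect_error(clade_scheme(NULL, list("1" = "A", "2" = "A"),
                            data.frame(clade = c("1","2"),
                                       phiVPE25 = "sensitive",
                                       phiVFW = "sensitive")),
               "overlap")
  expect_error(clade_scheme(NULL, list("1" = "A", "2" = "B"),
                            data.frame(clade = "1",
                                       phiVPE25 = "sensitive",
                                       phiVFW = "sensitive")),
               "cover every clade")
})
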