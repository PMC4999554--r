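# Builds the packaged synthetic reference gene: a stand-in for the
# E. faecalis V583 PIP gene (EF0858) with the real gene's geometry --
# a 2667-nt ORF encoding 888 aa plus a terminal stop, with the variable
# region at aa 342-494 (nt 1024-1482).  Deterministic; run from the
# package root with: Rscript data-raw/make_reference.R

set.seed(8580)
codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
stops <- c("TAA", "TAG", "TGA")
sense <- setdiff(codons, stops)

n_aa <- 888L
body <- sample(sense, n_aa - 1L, replace = TRUE)  # codons 2..888
gene <- paste(c("ATG", body, "TAA"), collapse = "")
stopifnot(nchar(gene) == 2667L)

lines <- c(">synthetic_V583_PIP_EF synthetic stand-in for EF0858 (2667 nt ORF, VR nt 1024-1482)",
           substring(gene, seq(1, nchar(gene), 60),
                     pmin(seq(60, nchar(gene) + 59, 60), nchar(gene))))
writeLines(lines, "inst/extdata/synthetic_v583_pipef.fasta")
cat("wrote inst/extdata/synthetic_v583_pipef.fasta\n")
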