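# Deterministic graded gene set: gene k holds two taxon blocks whose exact
# state counts diverge linearly with k, so the true heterogeneity ranking
# is the construction order (no sampling noise involved).
graded_genes <- function(n_genes = 30, p = 600) {
  genes <- list()
  for (k in seq_len(n_genes)) {
    base <- p / 4
    shift <- 2 * k  # counts moved from C to A in the second block
    c1 <- c(base, base, base, base)
    c2 <- c(base + shift, base - shift, base, base)
    genes[[sprintf("g%03d", k)]] <- heterogeneous_alignment(
      n = 4, counts1 = c1, counts2 = c2)
  }
  genes
}

test_that("per-gene scoring uses each gene's own dimensions", {
  genes <- list(
    homog = new_alignment(rbind(t1 = rep(c("A", "C", "G", "T"), 25),
                                t2 = rep(c("A", "C", "G", "T"), 25)),
                          dna_alphabet()),
    het = heterogeneous_alignment(n = 4))
  tbl <- score_partitions(genes)
  expect_s3_class(tbl, "rcfv_gene_table")
  expect_equal(tbl$gene, c("homog", "het"))
  expect_equal(tbl$n_taxa, c(2L, 4L))
  expect_identical(tbl$rcfv[tbl$gene == "homog"], 0)
  expect_gt(tbl$rcfv[tbl$gene == "het"], 0)
  expect_equal(tbl$c, c(4L, 4L))
  expect_error(score_partitions(list()), "no gene")
})

test_that("taxa without data in a gene are excluded from its n", {
  mat <- rbind(t1 = c("A", "C", "G", "T"), t2 = c("A", "C", "G", "A"),
               t3 = rep(NA_character_, 4))
  tbl <- score_partitions(list(g1 = new_alignment(mat, dna_alphabet())))
  expect_equal(tbl$n_taxa, 2L)
})

test_that("column duplication keeps raw RCFV and scales nRCFV by sqrt(2)", {
  g <- heterogeneous_alignment(n = 4)
  dup <- cbind(unclass(g), unclass(g))
  rownames(dup) <- rownames(g)
  tbl <- score_partitions(list(a = g,
                               b = new_alignment(dup, dna_alphabet())))
  expect_equal(tbl$rcfv[1], tbl$rcfv[2], tolerance = 1e-12)
  expect_equal(tbl$nrcfv[2], sqrt(2) * tbl$nrcfv[1], tolerance = 1e-12)
})

test_that("nRCFV ranking recovers a constructed heterogeneity gradient", {
  genes <- graded_genes()
  tbl <- score_partitions(genes)
  expect_identical(order(tbl$nrcfv), seq_len(nrow(tbl)))
  expect_identical(order(tbl$rcfv), seq_len(nrow(tbl)))
})

test_that("quantile binning follows the ascending equal-split rule", {
  genes <- graded_genes(12)
  tbl <- score_partitions(genes)
  q <- assign_quantiles(tbl, "nrcfv", k = 6)
  expect_equal(q$bin_sizes, rep(2L, 6))
  expect_equal(q$assignment$bin, rep(1:6, each = 2))
  # ascending: bin 1 holds the smallest values
  expect_identical(q$assignment$gene[1:2], c("g001", "g002"))

  # remainder goes one extra gene to the earliest bins: 638 -> 107,107,...
  fake <- data.frame(gene = sprintf("x%04d", 1:638), p = 100L,
                     rcfv = seq(0, 1, length.out = 638),
                     nrcfv = seq(0, 1, length.out = 638))
  q638 <- assign_quantiles(fake, "nrcfv", k = 6)
  expect_equal(q638$bin_sizes, c(107L, 107L, 106L, 106L, 106L, 106L))

  # ties are broken lexicographically by gene name
  tied <- data.frame(gene = c("b", "a", "d", "c"), p = 10L,
                     rcfv = rep(0.5, 4), nrcfv = rep(0.5, 4))
  qt <- assign_quantiles(tied, "nrcfv", k = 2)
  expect_equal(qt$assignment$gene, c("a", "b", "c", "d"))

  expect_error(assign_quantiles(tbl, "nrcfv", k = 0), "k must be")
  expect_error(assign_quantiles(tbl, "nrcfv", k = 13), "k must be")
})

test_that("selection comparison counts non-shared genes per bin", {
  genes <- graded_genes(12)
  tbl <- score_partitions(genes)
  q <- assign_quantiles(tbl, "nrcfv", k = 6)
  same <- compare_selections(q, q, tbl)
  expect_true(all(same$per_bin$pct_nonshared == 0))
  expect_true(all(same$crosstab == 0))
  expect_equal(same$per_bin$length_a, same$per_bin$length_b)

  # a hand-built permutation of bins: swap bins 1 and 2 wholesale
  q2 <- q
  q2$assignment$bin[q2$assignment$bin %in% c(1L, 2L)] <-
    3L - q2$assignment$bin[q2$assignment$bin %in% c(1L, 2L)]
  q2$assignment <- q2$assignment[order(q2$assignment$bin), ]
  cmp <- compare_selections(q, q2, tbl)
  expect_equal(cmp$per_bin$pct_nonshared, c(100, 100, 0, 0, 0, 0))
  expect_equal(cmp$crosstab[1, 2], 2L)  # b-bin 1 genes sit in a-bin 2
  expect_equal(cmp$crosstab[2, 1], 2L)
  # cross-tab row sums equal the non-shared counts
  expect_equal(unname(rowSums(cmp$crosstab)),
               unname(round(cmp$per_bin$pct_nonshared / 100 *
                       vapply(split(q2$assignment$gene, q2$assignment$bin),
                              length, integer(1)))))

  # antisymmetry with equal bin sizes
  cmp_rev <- compare_selections(q2, q, tbl)
  expect_equal(cmp_rev$per_bin$pct_nonshared, cmp$per_bin$pct_nonshared)

  q3 <- assign_quantiles(tbl[1:11, ], "nrcfv", k = 6)
  expect_error(compare_selections(q, q3, tbl), "same gene")
})

test_that("hand-counted example: rcfv vs nrcfv disagreement on mixed lengths", {
  # short heterogeneous genes and long homogeneous-ish genes push the two
  # metrics apart; verify percentages against an explicit hand count
  tbl <- data.frame(
    gene = sprintf("g%02d", 1:6), p = c(100, 200, 400, 800, 1600, 3200),
    rcfv = c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05),
    nrcfv = c(0.02, 0.03, 0.05, 0.04, 0.01, 0.06))
  qa <- assign_quantiles(tbl, "rcfv", k = 3)   # bins: (g6,g5),(g4,g3),(g2,g1)
  qb <- assign_quantiles(tbl, "nrcfv", k = 3)  # bins: (g5,g1),(g2,g4),(g3,g6)
  cmp <- compare_selections(qa, qb, tbl)
  # hand count: b-bins (g5,g1),(g2,g4),(g3,g6) vs a-bins (g6,g5),(g4,g3),(g2,g1)
  expect_equal(cmp$per_bin$pct_nonshared, c(50, 50, 100))
  expect_equal(cmp$per_bin$length_b, c(1600 + 100, 200 + 800, 400 + 3200))
  expect_equal(cmp$per_bin$length_a, c(3200 + 1600, 800 + 400, 200 + 100))
})

test_that("cumulative supermatrices concatenate genes over the taxon union", {
  g1 <- new_alignment(rbind(a = c("A", "C"), b = c("G", "T")),
                      dna_alphabet())
  g2 <- new_alignment(rbind(b = c("A", "A", "A"), c = c("C", "C", "C")),
                      dna_alphabet())
  g3 <- new_alignment(rbind(a = c("T", "T"), c = c("G", "G")),
                      dna_alphabet())
  genes <- list(g1 = g1, g2 = g2, g3 = g3)
  tbl <- score_partitions(genes)
  q <- assign_quantiles(tbl, "nrcfv", k = 3)

  all3 <- cumulative_dataset(q, genes, upto = 3)
  expect_equal(ncol(all3), 2 + 3 + 2)
  expect_equal(sort(rownames(all3)), c("a", "b", "c"))
  # per-taxon non-missing cells equal the sum over member genes
  expect_equal(sum(!is.na(unclass(all3)["a", ])), 4L)
  expect_equal(sum(!is.na(unclass(all3)["b", ])), 5L)
  expect_equal(sum(!is.na(unclass(all3)["c", ])), 5L)
  # gene boundaries are recorded 1-based inclusive and tile the matrix
  bd <- attr(all3, "boundaries")
  expect_equal(bd$end - bd$start + 1L,
               vapply(genes[bd$gene], ncol, integer(1)), ignore_attr = TRUE)
  expect_equal(sort(unlist(Map(seq, bd$start, bd$end))), 1:7,
               ignore_attr = TRUE)
  # a taxon absent from a gene is missing across that gene's columns
  g2_range <- bd[bd$gene == "g2", ]
  expect_true(all(is.na(unclass(all3)["a", g2_range$start:g2_range$end])))

  one <- cumulative_dataset(q, genes, upto = 1)
  expect_equal(ncol(one), ncol(genes[[q$assignment$gene[1]]]))
  expect_error(cumulative_dataset(q, genes, upto = 9), "upto")
})

test_that("gene directories and partition files load alignments", {
  dir <- tempfile(); dir.create(dir)
  write_raw_fasta(list(t1 = "ACGTAC", t2 = "ACGAAC"),
                  file.path(dir, "geneB.fasta"))
  write_raw_fasta(list(t1 = "GGTT", t2 = "GGTA"),
                  file.path(dir, "geneA.fa"))
  genes <- read_gene_dir(dir)
  expect_equal(names(genes), c("geneA", "geneB"))  # sorted
  expect_equal(ncol(genes$geneB), 6L)
  expect_error(read_gene_dir(tempfile()), "no FASTA")

  super <- new_alignment(
    rbind(t1 = strsplit("ACGTACGTAA", "")[[1]],
          t2 = strsplit("ACGAACGTCC", "")[[1]]), dna_alphabet())
  pf <- tempfile()
  writeLines(c("# partitions", "DNA, gene1 = 1-6", "gene2 = 7-10"), pf)
  parts <- split_by_partitions(super, pf)
  expect_equal(names(parts), c("gene1", "gene2"))
  expect_equal(ncol(parts$gene1), 6L)
  expect_identical(unclass(parts$gene2)[, ], unclass(super)[, 7:10])

  bad <- tempfile(); writeLines("gene1 = 5-99", bad)
  expect_error(split_by_partitions(super, bad), "outside")
  bad2 <- tempfile(); writeLines("gene1 : 1-4", bad2)
  expect_error(split_by_partitions(super, bad2), "malformed")
})
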