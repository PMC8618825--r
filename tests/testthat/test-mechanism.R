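test_that("paralog search finds exact duplicates and honours floors and ties", {
  set.seed(95)
  gc <- Biostrings::GENETIC_CODE
  aas <- setdiff(unique(gc), "*")
  mk <- function(n) paste(sample(aas, n, TRUE), collapse = "")
  prots <- Biostrings::AAStringSet(c(
    gA = mk(200), gC = mk(180), gD = mk(150)))
  prots <- c(prots, Biostrings::AAStringSet(c(gB = as.character(prots[["gA"]]))))
  hit <- find_parent("gA", prots)
  expect_identical(hit$parent_id, "gB")
  expect_equal(hit$identity, 100)
  ## two equal-scoring parents: deterministic choice by gene id
  prots2 <- c(prots, Biostrings::AAStringSet(c(gB2 = as.character(prots[["gA"]]))))
  hit2 <- find_parent("gA", prots2)
  expect_identical(hit2$parent_id, "gB")
  ## unrelated random proteins fall below the floor
  rnd <- Biostrings::AAStringSet(c(u1 = mk(150), u2 = mk(150),
                                   u3 = mk(150)))
  expect_null(find_parent("u1", rnd))
})

test_that("mechanism partition sums and percentages are consistent", {
  calls <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    mechanism = c(rep("dna_duplication", 6), rep("retroposition", 1),
                  rep("de_novo", 2), "unclassified"))
  s <- partition_summary(calls)
  expect_identical(s$n[s$mechanism == "dna_duplication"], 6L)
  expect_identical(sum(s$n[s$mechanism != "unclassified"]), 9L)
  expect_equal(s$pct[s$mechanism == "dna_duplication"], proportion(6, 9))
  ## single mechanism only
  one <- data.frame(gene_id = "g", mechanism = "de_novo")
  s1 <- partition_summary(one)
  expect_equal(s1$pct[s1$mechanism == "de_novo"], 100)
  ## empty input
  s0 <- partition_summary(calls[0, ])
  expect_true(all(s0$n == 0L))
})

test_that("CDS exon counting uses the longest transcript", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      placed = TRUE, cds_ok = TRUE)
  features <- rbind(
    data.frame(gene_id = "g1", transcript_id = "g1.t1",
               type = c("exon", "CDS", "exon", "CDS"), chrom = "chr1",
               start = c(1, 1, 201, 201), end = c(100, 100, 300, 300),
               strand = "+"),
    data.frame(gene_id = "g1", transcript_id = "g1.t2",
               type = c("exon", "CDS"), chrom = "chr1",
               start = 1, end = 90, strand = "+"))
  gm <- gene_models(genes, features)
  expect_identical(genorig:::cds_exon_counts(gm)[["g1"]], 2L)
})
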