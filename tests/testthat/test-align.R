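test_that("seed index enumerates k-mer positions, masks N and frequent k-mers", {
  idx <- build_seed_index(c(chr1 = "ACGTACGT"), k = 8)
  ## k = 8 window of an 8-mer: the sequence itself
  expect_identical(idx$chr1[["ACGTACGT"]], 1L)
  expect_error(build_seed_index(c(chr1 = "ACGT"), k = 4), "k must be")
  idx2 <- build_seed_index(c(chr1 = "ACGTNCGTAAAAAAA"), k = 8)
  expect_false(any(grepl("N", names(idx2$chr1))))
  polyA <- paste(rep("A", 100), collapse = "")
  idx3 <- build_seed_index(c(chr1 = polyA), k = 8, max_occ = 10)
  expect_length(idx3$chr1, 0)
})

test_that("identical sequences self-align as one near-complete chain", {
  s <- random_dna(10000, seed = 11)
  ch <- align_genomes(c(chr1 = s), c(q1 = s))
  best <- ch$chains[which.max(ch$chains$score), ]
  expect_gte((best$t_end - best$t_start + 1) / 10000, 0.99)
  expect_gte((best$q_end - best$q_start + 1) / 10000, 0.99)
  expect_identical(best$q_strand, "+")
  expect_equal(best$score, 10000)
})

test_that("a reverse-complement query aligns on the minus strand", {
  s <- random_dna(5000, seed = 12)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  ch <- align_genomes(c(chr1 = s), c(q1 = rc))
  best <- ch$chains[which.max(ch$chains$score), ]
  expect_identical(best$q_strand, "-")
  expect_gte((best$t_end - best$t_start + 1) / 5000, 0.99)
})

test_that("empty or too-short input yields no chains", {
  ch <- align_genomes(c(chr1 = "ACGT"), c(q1 = "ACGT"))
  expect_identical(nrow(ch$chains), 0L)
})

test_that("diverged sequences are recovered with high chain coverage", {
  s <- random_dna(10000, seed = 13)
  q <- mutate_dna(s, p = 0.10, n_indel = 10, seed = 14)
  f2q <- align_genomes(c(chr1 = s), c(q1 = q))
  q2f <- align_genomes(c(q1 = q), c(chr1 = s))
  net <- reciprocal_best_net(f2q, q2f)
  cov <- coverage_fraction(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000)), net)
  expect_gte(cov, 0.90)
})

test_that("chain scores match a quadratic Smith-Waterman oracle on 1 kb pairs", {
  ## the chain is a constrained (anchored, ungapped-block) alignment under
  ## the same scoring, so its score is bounded by the optimal local score
  ## and should come close to it
  for (seed in c(21, 22)) {
    s <- random_dna(1000, seed = seed)
    q <- mutate_dna(s, p = 0.05, n_indel = 2, seed = seed + 100)
    ch <- align_genomes(c(chr1 = s), c(q1 = q),
                        align_params(min_chain_score = 50L))
    chain_score <- max(ch$chains$score)
    sw <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(q), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 4, gapExtension = 1, scoreOnly = TRUE)
    expect_lte(chain_score, sw + 1e-6)
    expect_gte(chain_score, 0.9 * sw)
  }
})

test_that("chain scores are recomputable from blocks minus gap penalties", {
  s <- random_dna(6000, seed = 31)
  q <- mutate_dna(s, p = 0.08, n_indel = 6, seed = 32)
  p <- align_params()
  ch <- align_genomes(c(chr1 = s), c(q1 = q), p)
  top <- ch$chains[which.max(ch$chains$score), ]
  bl <- ch$blocks[ch$blocks$chain_id == top$chain_id, ]
  bl <- bl[order(bl$t_start), ]
  ## block scores: matches - mismatches, recomputed from the sequences
  sv <- strsplit(s, "")[[1]]; qv <- strsplit(q, "")[[1]]
  block_score <- function(i) {
    a <- sv[bl$t_start[i]:bl$t_end[i]]
    b <- qv[bl$q_start[i]:bl$q_end[i]]
    sum(a == b) - sum(a != b)
  }
  sc <- sum(vapply(seq_len(nrow(bl)), block_score, 0))
  if (nrow(bl) > 1) {
    dt <- bl$t_start[-1] - bl$t_end[-nrow(bl)] - 1
    dq <- bl$q_start[-1] - bl$q_end[-nrow(bl)] - 1
    gap <- abs(dt - dq)
    sc <- sc - sum((gap > 0) * (p$gap_open + p$gap_extend * gap))
  }
  ## trimming at block junctions can only have removed matches; allow the
  ## recomputed score to exceed the reported one by that trimming margin
  expect_gte(sc, top$score - 1e-6)
  expect_lte(abs(sc - top$score) / top$score, 0.05)
})

test_that("reciprocal-best netting flags 1:1 homologs and resolves duplicates", {
  s <- random_dna(4000, seed = 41)
  ## query carries two identical copies of one focal segment
  seg <- substr(s, 1001, 2000)
  q <- paste0(random_dna(500, seed = 42), seg, random_dna(500, seed = 43),
              seg, random_dna(500, seed = 44))
  f2q <- align_genomes(c(chr1 = s), c(q1 = q))
  q2f <- align_genomes(c(q1 = q), c(chr1 = s))
  net <- reciprocal_best_net(f2q, q2f)
  rb <- net$chains[net$chains$reciprocal_best, ]
  ## exactly one of the two equal copies wins, deterministically
  expect_identical(nrow(rb), 1L)
  net2 <- reciprocal_best_net(net, q2f)
  expect_identical(net2$chains$reciprocal_best, net$chains$reciprocal_best)

  ## disjoint homologies in the two directions produce no flags
  s2 <- random_dna(3000, seed = 45)
  q2 <- random_dna(3000, seed = 46)
  f2q2 <- align_genomes(c(chr1 = s2), c(q1 = q2))
  q2f2 <- align_genomes(c(q1 = q2), c(chr1 = s2))
  net0 <- reciprocal_best_net(f2q2, q2f2)
  expect_identical(sum(net0$chains$reciprocal_best), 0L)
})

test_that("coverage fractions are exact on crafted chains", {
  s <- random_dna(2000, seed = 51)
  f2q <- align_genomes(c(chr1 = s), c(q1 = s))
  q2f <- align_genomes(c(q1 = s), c(chr1 = s))
  net <- reciprocal_best_net(f2q, q2f)
  iv <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 1500), c(199, 1599)))
  expect_equal(coverage_fraction(iv, net), c(1, 1))
  none <- structure(list(
    chains = net$chains[0, ], blocks = net$blocks[0, ]),
    class = "alignment_chains")
  expect_equal(coverage_fraction(iv, none), c(0, 0))
  expect_error(
    coverage_fraction(GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10)),
                      net, chromosomes = "chr1"),
    "unknown chromosome")
})
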