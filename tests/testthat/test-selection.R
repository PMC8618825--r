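test_that("protein-guided codon alignment reproduces pal2nal behaviour", {
  cds <- random_cds(50, seed = 61)
  aln <- align_codons(cds, cds)
  expect_identical(aln$n_codons, 49L)          # terminal stop stripped
  expect_false(any(aln$a == "---"))
  ## one amino-acid deletion becomes one codon gap
  del <- paste0(substr(cds, 1, 30), substr(cds, 34, nchar(cds)))
  aln2 <- align_codons(cds, del)
  expect_identical(sum(aln2$b == "---"), 1L)
  expect_identical(sum(aln2$a == "---"), 0L)
  ## back-translation: ungapped codons reproduce the inputs
  expect_identical(paste(aln2$a[aln2$a != "---"], collapse = ""),
                   substr(cds, 1, nchar(cds) - 3))
  expect_identical(paste(aln2$b[aln2$b != "---"], collapse = ""),
                   substr(del, 1, nchar(del) - 3))
})

test_that("broken coding sequences are rejected with positions", {
  expect_error(align_codons("ATGGCCTA", "ATGGCCTAA"), "divisible by 3")
  withstop <- "ATGTAAGCCTAA"                 # internal TAA at codon 2
  expect_error(align_codons(withstop, withstop), "internal stop")
})

test_that("NG86 counting behaves on crafted pairs", {
  cds <- random_cds(100, seed = 62)
  aln <- align_codons(cds, cds)
  ng <- ng86_kaks(aln)
  expect_equal(ng$ka, 0)
  expect_equal(ng$ks, 0)
  ## one synonymous change (GGT -> GGC, both Gly)
  a <- random_cds(100, seed = 63)
  a <- swap_codon(a, 10, "GGT")
  b <- swap_codon(a, 10, "GGC")
  ng2 <- ng86_kaks(align_codons(a, b))
  expect_equal(ng2$ka, 0)
  expect_gt(ng2$ks, 0)
  expect_equal(ng2$Nd, 0)
  expect_equal(ng2$Sd, 1)
  ## one nonsynonymous change (GGT Gly -> GTT Val)
  b2 <- swap_codon(a, 10, "GTT")
  ng3 <- ng86_kaks(align_codons(a, b2))
  expect_equal(ng3$Sd, 0)
  expect_equal(ng3$Nd, 1)
  expect_gt(ng3$ka, 0)
})

test_that("NG86 agrees with an independent counting implementation", {
  skip_if_not_installed("seqinr")
  ## seqinr implements the related LWL-style counting; on moderately
  ## diverged pairs the two estimators must rank and roughly scale alike
  set.seed(64)
  ratios <- replicate(12, {
    pair <- simulate_codon_pair(300, t = runif(1, 0.1, 0.6), kappa = 2,
                                omega = runif(1, 0.1, 1))
    a <- paste(pair$a, collapse = ""); b <- paste(pair$b, collapse = "")
    aln <- align_codons(paste0(a, "TAA"), paste0(b, "TAA"))
    ng <- ng86_kaks(aln)
    sq <- seqinr::kaks(seqinr::as.alignment(
      2, c("a", "b"), tolower(c(a, b))))
    c(ng$ka, sq$ka[1], ng$ks, sq$ks[1])
  })
  expect_gt(cor(ratios[1, ], ratios[2, ]), 0.9)   # Ka agreement
  expect_gt(cor(ratios[3, ], ratios[4, ]), 0.9)   # Ks agreement
})

test_that("the likelihood at zero divergence matches the closed form", {
  cds <- random_cds(100, seed = 65)
  fit <- ml_kaks(align_codons(cds, cds))
  expect_lt(fit$t_hat, 1e-4)
  expect_equal(fit$lnL, 99 * log(1 / 61), tolerance = 1e-6)
})

test_that("likelihood-ratio p-values hit chi-square reference points", {
  expect_equal(lrt(-100, -100 - 3.841 / 2), 0.0500, tolerance = 1e-3)
  expect_equal(lrt(-100, -100), 1)
  expect_equal(lrt(-100, -105), 0.00157, tolerance = 1e-2)
  ## tiny negative 2-delta is clamped, larger is an optimizer failure
  expect_equal(lrt(-100.0001, -100), 1)
  expect_error(lrt(-101, -100), "optimizer")
})

test_that("the alternative model never fits worse than the null", {
  set.seed(66)
  for (om in c(0.3, 1.0)) {
    cnt <- simulate_codon_pair(200, t = 0.5, kappa = 2, omega = om,
                               as_counts = TRUE)
    alt <- genorig:::fit_gy94_counts(cnt)
    nul <- genorig:::fit_gy94_counts(cnt, fix_omega = 0.5)
    expect_gte(alt$lnL, nul$lnL - 1e-3)
  }
})

test_that("ML and NG86 rank Ka/Ks consistently across a simulated panel", {
  set.seed(67)
  n <- 40
  est <- t(replicate(n, {
    om <- exp(runif(1, log(0.05), log(2)))
    pair <- simulate_codon_pair(200, t = 0.5, kappa = 2, omega = om)
    aln <- align_codons(paste0(paste(pair$a, collapse = ""), "TAA"),
                        paste0(paste(pair$b, collapse = ""), "TAA"))
    ml <- ml_kaks(aln)
    ng <- ng86_kaks(aln)
    c(ml = ml$omega_hat, ng = ng$ka / max(ng$ks, 1e-6))
  }))
  expect_gte(cor(est[, "ml"], est[, "ng"], method = "spearman"), 0.8)
})

test_that("Ka/Ks exclusion filters flag the stated conditions", {
  row <- function(ka, ks, p = 0.01) data.frame(
    gene_id = "g", partner_id = "p", ka = ka, ks = ks,
    omega_hat = ka / max(ks, 1e-9), lnL_alt = 0, lnL_null = -4,
    p_value = p, null_omega = 0.5, n_codons = 100L, filtered = "none",
    verdict = NA_character_, stringsAsFactors = FALSE)
  res <- rbind(row(0.6, 1), row(0.1, 5.5), row(0.02, 0.1), row(0.04, 0.2),
               row(0.06, 0.3), row(0.08, 0.4), row(0.3, 3.0))
  out <- ks_filter(res)
  expect_identical(out$filtered[1], "ka_gt_0.5")
  expect_identical(out$filtered[2], "ks_gt_5")
  ## Ks = 3.0 lies beyond Q3 + 1.5 IQR = 0.7 of the surviving distribution
  expect_identical(out$filtered[7], "ks_iqr_outlier")
  expect_identical(out$filtered[3:6], rep("none", 4))
  ## verdict requires omega < null and p < 0.05 on unfiltered rows
  expect_true(all(out$verdict[out$filtered != "none"] == "filtered"))
  expect_identical(out$verdict[3], "negative_selection")
  expect_warning(out2 <- ks_filter(rbind(row(0.3, 0.2, p = 0.2))),
                 "IQR filter skipped")
  expect_identical(out2$verdict[1], "not_significant")
})

test_that("verdicts are monotone in the significance threshold", {
  set.seed(68)
  rows <- do.call(rbind, lapply(1:12, function(i) {
    pair <- simulate_codon_pair(150, t = 0.4, kappa = 2,
                                omega = exp(runif(1, log(0.1), log(1))))
    selection_test(paste0(paste(pair$a, collapse = ""), "TAA"),
                   paste0(paste(pair$b, collapse = ""), "TAA"),
                   ids = c(paste0("g", i), "p"))
  }))
  v1 <- ks_filter(rows, alpha = 0.05)
  v2 <- ks_filter(rows, alpha = 0.01)
  neg1 <- v1$gene_id[v1$verdict == "negative_selection"]
  neg2 <- v2$gene_id[v2$verdict == "negative_selection"]
  expect_true(all(neg2 %in% neg1))
})

test_that("short alignments are flagged too_short, not tested", {
  a <- random_cds(20, seed = 69)
  r <- selection_test(a, a)
  expect_identical(r$filtered, "too_short")
  expect_identical(r$verdict, "filtered")
})

test_that("orthologous ORFs are recovered from a sister region", {
  set.seed(70)
  orf <- random_cds(120, seed = 71)
  prot <- sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAString(orf))))
  genome <- Biostrings::DNAStringSet(c(chrS = paste0(
    random_dna(3000, seed = 72), orf, random_dna(3000, seed = 73))))
  hit <- de_novo_ortholog_orf(prot, genome, "chrS", 3001, 3000 + nchar(orf))
  expect_false(is.null(hit))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot), Biostrings::AAString(hit$protein),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "local")
  expect_gte(Biostrings::pid(al), 95)

  ## stop-disrupted ortholog: no acceptable ORF
  broken <- paste0(substr(orf, 1, 150), "TAA", substr(orf, 154, nchar(orf)))
  mid <- paste0(substr(broken, 1, 180), "TGA", substr(broken, 184, nchar(broken)))
  genome2 <- Biostrings::DNAStringSet(c(chrS = paste0(
    random_dna(500, seed = 74), mid, random_dna(500, seed = 75))))
  hit2 <- de_novo_ortholog_orf(prot, genome2, "chrS", 501, 500 + nchar(mid),
                               flank = 200)
  ## fragments may persist above 30 codons; any hit must itself be stop-free
  if (!is.null(hit2)) {
    expect_false(grepl("*", hit2$protein, fixed = TRUE))
    expect_lt(nchar(hit2$protein), nchar(prot))
  }

  ## region at the chromosome edge truncates the flank without error
  hit3 <- de_novo_ortholog_orf(prot, genome, "chrS", 1, 100)
  expect_error(de_novo_ortholog_orf(prot, genome, "chrS", 99999, 100010),
               "outside")
})
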