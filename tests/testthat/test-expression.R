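fpkm_em <- function(m) {
  expression_matrix(m, "fpkm")
}

test_that("expression calls use replicate means and a strict threshold", {
  m <- matrix(c(0.6, 0.6,  0, 0,  0, 0,
                0.5, 0.5,  0.5, 0.5,  0.5, 0.5,
                0, 0,  0, 0,  0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("a.1", "a.2", "b.1", "b.2", "c.1", "c.2")))
  calls <- call_expression(fpkm_em(m))
  expect_identical(calls$expressed, c(TRUE, FALSE, FALSE))   # 0.5 is not > 0.5
  expect_identical(calls$breadth, c(1L, 0L, 0L))
  ## replicate averaging: 0.4 and 0.8 average to 0.6 > 0.5
  m2 <- matrix(c(0.4, 0.8), 1, 2,
               dimnames = list("g1", c("a.1", "a.2")))
  expect_true(call_expression(fpkm_em(m2))$expressed)
})

test_that("expressed counts are monotone non-increasing in the threshold", {
  set.seed(81)
  m <- matrix(rlnorm(300, 0, 1.5) * rbinom(300, 1, 0.8), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50),
                              paste0(rep(c("a", "b", "c"), each = 2), ".",
                                     rep(1:2, 3))))
  em <- fpkm_em(m)
  counts <- vapply(c(0.1, 0.5, 1, 2, 5),
                   function(th) sum(call_expression(em, th)$expressed), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("age-group contrast behaves under the null and on small groups", {
  set.seed(82)
  m <- matrix(rlnorm(400, 1, 1), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100),
                              c("a.1", "a.2", "b.1", "b.2")))
  em <- fpkm_em(m)
  ages <- data.frame(gene_id = rownames(m),
                     branch = rep(c(0L, 5L), each = 50))
  ## identical distributions: two-sided rank-sum p is far from significant
  r <- age_group_stats(ages, em)
  expect_gt(r$p_value, 0.05)
  expect_identical(sort(r$summary$group), c("old", "young"))
  ## a group of one still yields a valid p-value
  ages1 <- data.frame(gene_id = rownames(m),
                      branch = c(0L, rep(5L, 99)))
  r1 <- age_group_stats(ages1, em)
  expect_true(is.finite(r1$p_value))
  expect_error(age_group_stats(data.frame(gene_id = rownames(m),
                                          branch = 0L), em), "non-empty")
})

test_that("de novo tissue breakdown conserves counts", {
  m <- matrix(c(2, 2, 2,      # all three tissues
                2, 0, 0,      # single
                2, 2, 0,      # multi
                0, 0, 0),     # silent
              4, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:4),
                              c("a.1", "b.1", "c.1")))
  calls <- call_expression(fpkm_em(m))
  d <- de_novo_tissue_counts(calls)
  expect_identical(d$n_expressed, 3L)
  expect_identical(d$all_tissues, 1L)
  expect_identical(d$single_tissue, 1L)
  expect_identical(d$multi_tissue, 1L)
  expect_identical(d$all_tissues + d$single_tissue + d$multi_tissue,
                   d$n_expressed)
  expect_equal(unname(d$per_tissue), c(3, 2, 1))
})

test_that("the NB Wald test is exact on degenerate input and symmetric", {
  cnt <- matrix(rep(c(5L, 9L, 7L), each = 6), 3, 6, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), NULL))
  r <- nb_differential_test(cnt, c("L", "L", "L", "R", "R", "R"))
  expect_true(all(abs(r$lfc) < 1e-9))
  expect_true(all(r$p_value > 0.99))
  ## all-zero gene: defined result, no error
  cnt0 <- rbind(cnt, g0 = rep(0L, 6))
  r0 <- nb_differential_test(cnt0, c("L", "L", "L", "R", "R", "R"))
  expect_identical(r0$p_value[4], 1)
  expect_identical(r0$lfc[4], 0)
  ## swapping sides negates the fold change and keeps the p-value
  set.seed(83)
  cnt2 <- matrix(rnbinom(600, mu = 50, size = 20), 100, 6,
                 dimnames = list(sprintf("g%03d", 1:100), NULL))
  a <- nb_differential_test(cnt2, c("L", "L", "L", "R", "R", "R"))
  b <- nb_differential_test(cnt2, c("R", "R", "R", "L", "L", "L"))
  expect_equal(a$lfc, -b$lfc)
  expect_equal(a$p_value, b$p_value)
})

test_that("size factors undo library-size distortions", {
  set.seed(84)
  base <- rnbinom(500, mu = 100, size = 20)
  cnt <- cbind(base, base * 2L, base, base * 4L)
  rownames(cnt) <- sprintf("g%03d", 1:500)
  sf <- size_factors(cnt)
  expect_equal(sf / sf[1], c(1, 2, 1, 4), tolerance = 0.05)
})

test_that("the NB test agrees with DESeq2 on strong planted signals", {
  skip_if_not_installed("DESeq2")
  set.seed(85)
  n <- 400; de <- 1:60
  mu <- exp(rnorm(n, log(100), 1))
  fold <- rep(1, n); fold[de] <- 4
  L <- matrix(rnbinom(n * 3, mu = rep(mu, 3), size = 20), n, 3)
  R <- matrix(rnbinom(n * 3, mu = rep(mu * fold, 3), size = 20), n, 3)
  cnt <- cbind(L, R)
  rownames(cnt) <- sprintf("g%03d", 1:n)
  colnames(cnt) <- paste0("s", 1:6)
  side <- c("L", "L", "L", "R", "R", "R")
  ours <- nb_differential_test(cnt, side)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt, S4Vectors::DataFrame(side = factor(side)), ~side)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- DESeq2::results(dds)
  expect_gte(mean(ours$p_value[de] < 0.05), 0.8)
  expect_gte(mean(ref$pvalue[de] < 0.05, na.rm = TRUE), 0.8)
  ## the two tests call overlapping significant sets
  both <- sum(ours$p_value[de] < 0.05 & ref$pvalue[de] < 0.05, na.rm = TRUE)
  expect_gte(both / length(de), 0.75)
  ## and comparable fold-change estimates on the planted genes
  expect_gt(cor(ours$lfc[de], ref$log2FoldChange[de]), 0.8)
})

test_that("per-stage/tissue asymmetry scan returns one row per gene and combo", {
  set.seed(86)
  combos <- expand.grid(rep = 1:3, side = c("L", "R"),
                        stage = c("Pre", "Pro"), tissue = c("eye", "muscle"))
  cn <- with(combos, paste(tissue, side, stage, rep, sep = "."))
  cnt <- matrix(rnbinom(20 * length(cn), mu = 60, size = 20), 20,
                length(cn), dimnames = list(sprintf("g%02d", 1:20), cn))
  em <- expression_matrix(cnt, "counts")
  deg <- asymmetry_tests(em)
  expect_identical(nrow(deg), 20L * 4L)
  expect_identical(sort(unique(paste(deg$stage, deg$tissue))),
                   sort(paste(c("Pre", "Pro", "Pre", "Pro"),
                              c("eye", "eye", "muscle", "muscle"))))
})
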