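## build a minimal netted chain set: one reciprocal-best chain per species
## whose single block covers a stated fraction of each exon
fake_chains <- function(cov_by_exon, exons) {
  ## cov_by_exon: numeric vector, fraction of each exon covered
  bl <- lapply(seq_len(nrow(exons)), function(i) {
    w <- round((exons$end[i] - exons$start[i] + 1) * cov_by_exon[i])
    if (w == 0) return(NULL)
    data.frame(chain_id = 1L, t_chrom = exons$chrom[i],
               t_start = exons$start[i], t_end = exons$start[i] + w - 1L,
               q_chrom = "q1", q_start = exons$start[i],
               q_end = exons$start[i] + w - 1L)
  })
  bl <- do.call(rbind, bl[!vapply(bl, is.null, TRUE)])
  if (is.null(bl)) bl <- data.frame(chain_id = integer(0),
                                    t_chrom = character(0),
                                    t_start = integer(0), t_end = integer(0),
                                    q_chrom = character(0),
                                    q_start = integer(0), q_end = integer(0))
  ch <- data.frame(chain_id = 1L, t_chrom = "chr1", t_start = 1L,
                   t_end = 10000L, q_chrom = "q1", q_start = 1L,
                   q_end = 10000L, q_strand = "+", score = 1000,
                   reciprocal_best = TRUE)
  structure(list(chains = ch[nrow(bl) > 0, , drop = FALSE], blocks = bl),
            class = "alignment_chains")
}

test_that("presence calls threshold per-exon coverage", {
  gm <- toy_gene_models()
  ex <- unique(gm$features[gm$features$type == "exon",
                           c("gene_id", "chrom", "start", "end")])
  chains <- list(sp1 = fake_chains(c(0.6, 0.1, 0.0), ex))
  prof <- call_presence(gm, chains, threshold = 0.5)
  p1 <- prof[prof$gene_id == "g1", ]
  expect_identical(p1$present, c(TRUE, FALSE))     # 0.6 yes, 0.1 no
  expect_identical(prof$present[prof$gene_id == "g2"], FALSE)
  ## boundary: coverage exactly at the threshold counts as present
  chains2 <- list(sp1 = fake_chains(c(0.5, 0, 0), ex))
  prof2 <- call_presence(gm, chains2, threshold = 0.5)
  expect_true(prof2$present[prof2$gene_id == "g1"][1])
})

test_that("branch assignment follows Dollo parsimony with the oldest-exon rule", {
  l <- default_ladder()
  others <- setdiff(l$taxa, "focal")
  prof_row <- function(gene, exon, sp, pres) data.frame(
    gene_id = gene, exon_id = exon, species = sp, coverage = as.numeric(pres),
    present = pres)
  ## exon 1 present back to sp4 (branch 2), exon 2 only in sister
  ## (branch 4): the gene takes the oldest exon age, branch 2
  prof <- rbind(
    do.call(rbind, lapply(others, function(sp)
      prof_row("g1", 1L, sp, sp %in% c("sister", "sp3", "sp4")))),
    do.call(rbind, lapply(others, function(sp)
      prof_row("g1", 2L, sp, sp == "sister"))))
  calls <- assign_branch(prof, l)
  expect_identical(calls$branch, 2L)
  ## all species present -> 0; none -> terminal branch
  prof0 <- do.call(rbind, lapply(others, function(sp) prof_row("g0", 1L, sp, TRUE)))
  prof5 <- do.call(rbind, lapply(others, function(sp) prof_row("g5", 1L, sp, FALSE)))
  expect_identical(assign_branch(prof0, l)$branch, 0L)
  expect_identical(assign_branch(prof5, l)$branch, 5L)
  ## incomplete profiles are rejected
  expect_error(assign_branch(prof0[-1, ], l), "cover all ladder taxa")
})

test_that("exclusion filters apply the strict 70% repeat rule and placement", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      chrom = c("chr1", "chr1", "scaf1"),
                      strand = "+", placed = c(TRUE, TRUE, FALSE),
                      cds_ok = TRUE)
  features <- data.frame(
    gene_id = rep(c("gA", "gB", "gC"), each = 2),
    transcript_id = rep(paste0(c("gA", "gB", "gC"), ".t1"), each = 2),
    type = rep(c("exon", "CDS"), 3),
    chrom = rep(c("chr1", "chr1", "scaf1"), each = 2),
    start = rep(c(1L, 1001L, 1L), each = 2),
    end = rep(c(1000L, 2000L, 1000L), each = 2), strand = "+")
  gm <- gene_models(genes, features)
  calls <- data.frame(gene_id = c("gA", "gB", "gC"), branch = 5L,
                      excluded = FALSE, exclusion_reason = "none")
  ## gA: 750/1000 repeat bases (> 0.70 -> excluded);
  ## gB: exactly 700/1000 (not > 0.70 -> retained)
  reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1001),
                                                          c(750, 1700)))
  out <- apply_filters(calls, gm, reps)
  expect_identical(out$exclusion_reason,
                   c("repeat_overlap", "none", "unplaced"))
  expect_identical(out$excluded, c(TRUE, FALSE, TRUE))
})

test_that("emergence rates and proportions compute and guard their domains", {
  expect_equal(emergence_rate(0, 10), 0)
  expect_error(emergence_rate(10, 0), "positive")
  expect_equal(proportion(0, 100), 0)
  expect_error(proportion(1, 0), "positive")
  expect_error(proportion(5, 4), "within")
})

test_that("non-excluded genes partition exactly across branches", {
  set.seed(91)
  l <- default_ladder()
  others <- setdiff(l$taxa, "focal")
  genes <- sprintf("g%03d", 1:40)
  prof <- do.call(rbind, lapply(genes, function(g) {
    pres <- setNames(runif(7) < 0.5, others)
    data.frame(gene_id = g, exon_id = 1L, species = others,
               coverage = as.numeric(pres), present = unname(pres))
  }))
  calls <- assign_branch(prof, l)
  expect_identical(sort(calls$gene_id), genes)
  expect_true(all(calls$branch >= 0 & calls$branch <= l$n_branches))
  calls$excluded <- FALSE
  bs <- branch_summary(calls, l)
  expect_identical(sum(bs$per_branch$n), 40L)
  expect_identical(bs$n_total, 40L)
})
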