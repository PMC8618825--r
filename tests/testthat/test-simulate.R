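cfg_small <- function(...) {
  simulation_config(seed = 5L, n_chromosomes = 1L,
                    chromosome_length = 1.5e5, n_ancestral_genes = 20L,
                    n_unplaced_genes = 0L, ...)
}

test_that("the ancestral genome carries the requested number of valid ORFs", {
  cfg <- simulation_config(seed = 3L, n_chromosomes = 1L,
                           chromosome_length = 6e5,
                           n_ancestral_genes = 50L)
  set.seed(cfg$seed)
  anc <- simulate_ancestral_genome(cfg)
  expect_identical(nrow(anc$genes), 50L)
  gm <- gene_models(cbind(anc$genes[, c("gene_id", "chrom", "strand")],
                          placed = TRUE, cds_ok = TRUE), anc$features)
  genome <- Biostrings::DNAStringSet(
    vapply(anc$seqs, function(v) paste(c("A", "C", "G", "T")[v],
                                       collapse = ""), ""))
  aa <- as.character(Biostrings::translate(cds_sequences(gm, genome)))
  expect_length(aa, 50L)
  expect_true(all(substr(aa, 1, 1) == "M"))
  expect_true(all(substr(aa, nchar(aa), nchar(aa)) == "*"))
  expect_false(any(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)))
})

test_that("a zero-gene config yields a pure intergenic genome", {
  cfg <- simulation_config(seed = 4L, n_chromosomes = 1L,
                           chromosome_length = 2e4, n_ancestral_genes = 0L,
                           repeat_density = 0)
  set.seed(cfg$seed)
  anc <- simulate_ancestral_genome(cfg)
  expect_identical(nrow(anc$features), 0L)
  expect_length(anc$seqs$chr1, 2e4L)
})

test_that("over-full chromosomes are rejected with advice", {
  cfg <- simulation_config(seed = 4L, n_chromosomes = 1L,
                           chromosome_length = 1e4,
                           n_ancestral_genes = 50L)
  set.seed(cfg$seed)
  expect_error(simulate_ancestral_genome(cfg), "chromosome_length")
})

test_that("evolution at rate zero is the identity", {
  cfg <- cfg_small(substitution_rate = 0, indel_rate = 0)
  set.seed(cfg$seed)
  anc <- simulate_ancestral_genome(cfg)
  ev <- evolve_branch(anc, 50, cfg)
  expect_identical(ev$seqs, anc$seqs)
  expect_identical(ev$features, anc$features)
})

test_that("neutral divergence matches the configured substitution rate", {
  ## 20 kb of pure intergenic sequence, no indels: the per-site
  ## substitution probability after rate * t = 0.02 expected hits is
  ## 1 - exp(-0.02) (HKY proposals never propose the current base)
  cfg <- simulation_config(seed = 6L, n_chromosomes = 1L,
                           chromosome_length = 2e4, n_ancestral_genes = 0L,
                           repeat_density = 0, indel_rate = 0,
                           substitution_rate = 0.002)
  set.seed(cfg$seed)
  anc <- simulate_ancestral_genome(cfg)
  ev <- evolve_branch(anc, 10, cfg)
  div <- mean(ev$seqs$chr1 != anc$seqs$chr1)
  p <- 1 - exp(-0.02)
  se <- sqrt(p * (1 - p) / 2e4)
  expect_lt(abs(div - p), 4 * se)
})

test_that("coding evolution never breaks open reading frames", {
  cfg <- cfg_small(substitution_rate = 2e-3)  # hot: ~17% per branch
  sim <- simulate_genomes(cfg)
  gm <- sim$models[[sim$ladder$focal]]
  aa <- as.character(Biostrings::translate(
    cds_sequences(gm, sim$genomes[[sim$ladder$focal]])))
  expect_false(any(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)))
  expect_true(all(substr(aa, 1, 1) == "M"))
})

test_that("simulation output is byte-deterministic in the seed", {
  cfg <- cfg_small()
  sim1 <- simulate_genomes(cfg)
  sim2 <- simulate_genomes(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(sim1, d1)
  write_simulation(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("planted events conserve the configured counts per branch and mechanism", {
  cfg <- cfg_small()
  sim <- simulate_genomes(cfg)
  got <- as.data.frame(table(branch = sim$truth$true_branch,
                             mechanism = sim$truth$true_mechanism),
                       stringsAsFactors = FALSE)
  got <- got[got$Freq > 0, ]
  want <- cfg$events[cfg$events$count > 0, ]
  for (i in seq_len(nrow(want))) {
    hit <- got$branch == want$branch[i] & got$mechanism == want$mechanism[i]
    expect_identical(sum(got$Freq[hit]), as.integer(want$count[i]))
  }
  ## retroposition children are single-CDS-exon copies of multi-exon parents
  f <- sim$models[[sim$ladder$focal]]$features
  retro <- sim$truth[sim$truth$true_mechanism == "retroposition", ]
  for (i in seq_len(nrow(retro))) {
    nc_child <- sum(f$gene_id == retro$gene_id[i] & f$type == "CDS")
    nc_parent <- sum(f$gene_id == retro$parent_gene_id[i] & f$type == "CDS")
    expect_identical(nc_child, 1L)
    expect_gte(nc_parent, 2L)
  }
  ## de novo events have no parent
  expect_true(all(is.na(
    sim$truth$parent_gene_id[sim$truth$true_mechanism == "de_novo"])))
})

test_that("plant_event copies structures correctly and rejects bad parents", {
  cfg <- cfg_small()
  set.seed(cfg$seed)
  anc <- simulate_ancestral_genome(cfg)
  anc$genes$omega <- anc$genes$omega
  n_cds <- table(anc$features$gene_id[anc$features$type == "CDS"])
  multi <- names(n_cds)[n_cds >= 3][1]
  single <- names(n_cds)[n_cds == 1][1]
  ## DNA duplication of a 3+-exon parent copies the exon structure
  pl <- plant_event(anc, "childD", "dna_duplication", 5L, 0.2, cfg,
                    parent_id = multi)
  nf <- pl$state$features
  expect_identical(sum(nf$gene_id == "childD" & nf$type == "CDS"),
                   as.integer(n_cds[[multi]]))
  ## retroposition inserts the spliced CDS as one exon
  pl2 <- plant_event(anc, "childR", "retroposition", 5L, 0.2, cfg,
                     parent_id = multi)
  nf2 <- pl2$state$features[pl2$state$features$gene_id == "childR", ]
  cds_len <- sum(with(anc$features,
                      end - start + 1)[anc$features$gene_id == multi &
                                         anc$features$type == "CDS"])
  expect_identical(nrow(nf2[nf2$type == "CDS", ]), 1L)
  expect_identical(nf2$end[1] - nf2$start[1] + 1L, as.integer(cds_len))
  ## retroposition demands a multi-exon parent
  expect_error(plant_event(anc, "x", "retroposition", 5L, 0.2, cfg,
                           parent_id = single), "multi-exon")
})

test_that("expression generator honours silencing and fold-change design", {
  cfg <- cfg_small()
  sim <- simulate_genomes(cfg)
  ## silent genes are zero across every FPKM and count column
  silent <- sim$expr_truth$gene_id[sim$expr_truth$silent]
  if (length(silent)) {
    expect_true(all(sim$fpkm$values[silent, ] == 0))
    expect_true(all(sim$counts$values[silent, ] == 0))
  }
  ## the planted fold change appears only at the configured stage/tissue
  asym <- sim$expr_truth$gene_id[sim$expr_truth$asymmetric]
  meta <- sim$counts$meta
  at <- meta$stage == cfg$asym_stage & meta$tissue == cfg$asym_tissue
  v <- sim$counts$values
  ratio_at <- mean(v[asym, at & meta$side == "R"]) /
    mean(v[asym, at & meta$side == "L"])
  ratio_off <- mean(v[asym, !at & meta$side == "R"]) /
    mean(v[asym, !at & meta$side == "L"])
  expect_gt(ratio_at, 2.5)
  expect_lt(abs(log2(ratio_off)), 0.5)
})

test_that("the planted fold change is unbiased across many generated genes", {
  ## Monte-Carlo check of the count generator itself: 1000 planted genes
  genes <- data.frame(gene_id = sprintf("g%04d", 1:1100), chrom = "chr1",
                      strand = "+", placed = TRUE, cds_ok = TRUE)
  features <- data.frame(gene_id = genes$gene_id,
                         transcript_id = paste0(genes$gene_id, ".t1"),
                         type = "exon", chrom = "chr1",
                         start = seq(1, by = 200, length.out = 1100),
                         end = seq(100, by = 200, length.out = 1100),
                         strand = "+")
  gm <- gene_models(genes, features)
  truth <- data.frame(gene_id = genes$gene_id[1:1050], true_branch = 3L,
                      true_mechanism = "dna_duplication",
                      parent_gene_id = NA, true_omega = 0.5)
  cfg <- simulation_config(seed = 9L, n_asym_genes = 1000L,
                           frac_young_silent = 0)
  set.seed(cfg$seed)
  ex <- simulate_expression(gm, truth, cfg)
  asym <- ex$truth$gene_id[ex$truth$asymmetric]
  expect_identical(length(asym), 1000L)
  meta <- ex$counts$meta
  at <- meta$stage == cfg$asym_stage & meta$tissue == cfg$asym_tissue
  mR <- rowMeans(ex$counts$values[asym, at & meta$side == "R"])
  mL <- rowMeans(ex$counts$values[asym, at & meta$side == "L"])
  ratio <- mean(mR / pmax(mL, 1))
  expect_lt(abs(ratio - cfg$asym_fold), 0.35)
})
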