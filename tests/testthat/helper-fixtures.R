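## Shared fixtures: all built in code, deterministically.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## mutate a sequence: point substitutions at rate p, plus n_indel short
## indels (returns the mutated character string)
mutate_dna <- function(s, p = 0.1, n_indel = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(s, "")[[1]]
  i <- which(stats::runif(length(v)) < p)
  if (length(i)) v[i] <- sample(c("A", "C", "G", "T"), length(i), TRUE)
  if (n_indel > 0) {
    for (k in seq_len(n_indel)) {
      pos <- sample(length(v) - 12L, 1L)
      len <- sample(1:8, 1L)
      if (stats::runif(1) < 0.5) v <- v[-(pos:(pos + len))]
      else v <- append(v, sample(c("A", "C", "G", "T"), len, TRUE),
                       after = pos)
    }
  }
  paste(v, collapse = "")
}

## a small two-gene annotation on one chromosome (plus strand), with one
## two-exon gene and one single-exon gene
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    placed = TRUE, cds_ok = TRUE)
  features <- rbind(
    data.frame(gene_id = "g1", transcript_id = "g1.t1",
               type = c("exon", "CDS", "exon", "CDS"), chrom = "chr1",
               start = c(101, 101, 301, 301), end = c(202, 202, 399, 399),
               strand = "+"),
    data.frame(gene_id = "g2", transcript_id = "g2.t1",
               type = c("exon", "CDS"), chrom = "chr1",
               start = 1001, end = 1300, strand = "+"))
  gene_models(genes, features)
}

## random CDS of n codons: ATG + sense codons + stop
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- setdiff(names(gc)[gc != "*"], "ATG")
  paste0("ATG", paste(sample(sense, n_codons - 2L, TRUE), collapse = ""),
         "TAA")
}

## apply n synonymous-preserving random codon substitutions is overkill for
## most tests; this helper substitutes whole codons at given positions
swap_codon <- function(cds, at, new) {
  substr(cds, (at - 1L) * 3L + 1L, at * 3L) <- new
  cds
}

## tiny simulation config for fast pipeline-level tests
tiny_config <- function(seed = 7L, ...) {
  simulation_config(
    seed = seed, n_chromosomes = 1L, chromosome_length = 1.2e5,
    n_ancestral_genes = 18L,
    events = data.frame(
      branch = c(3L, 5L, 3L, 5L),
      mechanism = c("dna_duplication", "retroposition", "de_novo",
                    "de_novo"),
      count = c(2L, 1L, 1L, 1L)),
    n_unplaced_genes = 1L, frac_young_silent = 0, n_asym_genes = 3L, ...)
}

## independent exhaustive Dollo-parsimony oracle: a gene present in a set
## of species originated on the oldest branch compatible with a single
## gain; equivalently the youngest branch whose descendant set contains
## all carriers.  Implemented by direct enumeration over branches using
## only the clade lists, independently of dollo_branch's arithmetic.
dollo_oracle <- function(present_taxa, ladder) {
  B <- ladder$n_branches
  ## descendants of branch b = focal + clades shed at splits b+1..B
  for (b in B:0) {
    desc <- ladder$focal
    if (b < B) {
      for (i in (b + 1L):B) desc <- c(desc, ladder$splits$clade[[i]])
    }
    if (all(present_taxa %in% desc)) return(b)
  }
  stop("unreachable")
}
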