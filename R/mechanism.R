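#' Find the closest paralog of a gene in the focal proteome
#'
#' Local protein alignment (BLOSUM62, affine gaps 11/1) of the gene's
#' protein against every other protein; hits must cover at least
#' `min_coverage` of the shorter protein and score at least `score_floor`.
#' Ties are broken by (score, gene id) so the choice is deterministic.
#'
#' @param gene_id the query gene.
#' @param prots named [Biostrings::AAStringSet] (the focal proteome from
#'   [proteome]).
#' @param score_floor minimum alignment score (default 50).
#' @param min_coverage minimum fraction of the shorter protein covered by
#'   the local alignment (default 0.3).
#' @return `NULL` if no acceptable paralog, else list with `parent_id`,
#'   `score`, `identity` (percent over the aligned region).
#' @export
find_parent <- function(gene_id, prots, score_floor = 50,
                        min_coverage = 0.3) {
  if (!gene_id %in% names(prots)) {
    stop("gene ", gene_id, " has no protein (missing or invalid CDS)")
  }
  self <- prots[[gene_id]]
  others <- prots[setdiff(names(prots), gene_id)]
  if (length(others) == 0L) return(NULL)
  al <- Biostrings::pairwiseAlignment(
    others, self, substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = "local")
  sc <- Biostrings::score(al)
  ## coverage of the shorter protein by the aligned region
  wpat <- IRanges::width(Biostrings::pattern(al))   # aligned incl gaps
  shorter <- pmin(Biostrings::width(others), length(self))
  aligned_pat <- nchar(gsub("-", "", as.character(
    Biostrings::alignedPattern(al)), fixed = TRUE))
  aligned_sub <- nchar(gsub("-", "", as.character(
    Biostrings::alignedSubject(al)), fixed = TRUE))
  covered <- pmin(aligned_pat, aligned_sub) / shorter
  ok <- sc >= score_floor & covered >= min_coverage
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  best <- cand[order(-sc[cand], names(others)[cand])][1L]
  list(parent_id = names(others)[best], score = sc[best],
       identity = Biostrings::pid(al[best]))
}

cds_exon_counts <- function(gm) {
  f <- gm$features[gm$features$type == "CDS", , drop = FALSE]
  ## count CDS exons of the longest transcript per gene
  len_by_tx <- tapply(f$end - f$start + 1L, f$transcript_id, sum)
  tx2gene <- vapply(split(f$gene_id, f$transcript_id), `[`, "", 1L)
  n_by_tx <- table(f$transcript_id)
  best_tx <- tapply(names(len_by_tx), tx2gene[names(len_by_tx)],
                    function(tids) tids[which.max(len_by_tx[tids])])
  stats::setNames(as.integer(n_by_tx[unlist(best_tx)]), names(best_tx))
}

#' Classify the origin mechanism of lineage-specific genes
#'
#' A gene with a paralog is a retrogene when the parent has at least 2
#' CDS exons and the child exactly 1 (intron loss through an mRNA
#' intermediate), otherwise a DNA-mediated duplicate.  A gene without a
#' paralog is de novo when at least one pre-origination species (a species
#' that split before the gene's branch) carries reciprocal-best homologous
#' sequence over the gene's exons with no annotated gene at the homologous
#' location; otherwise it is reported unclassified.
#'
#' @param ages filtered age calls ([apply_filters]); only non-excluded
#'   genes on branches `lineage_min..B` are classified.
#' @param gm focal [gene_models].
#' @param genome focal genome.
#' @param species_chains named list of netted `alignment_chains`.
#' @param query_models named list of [gene_models] for the query species
#'   (used to check for annotated genes at homologous locations).
#' @param ladder a [species_ladder].
#' @param lineage_min first lineage-specific branch (default 2).
#' @param noncoding_min minimum reciprocal-best exon coverage accepted as
#'   evidence of homologous sequence in a pre-origination species
#'   (default 0.05; must be below the presence threshold used for
#'   dating).
#' @param score_floor,min_coverage passed to [find_parent].
#' @param external_homology optional character vector of gene ids with
#'   known protein homology in external databases; such genes are never
#'   called de novo (veto), they are reported unclassified instead.
#' @return data.frame with `gene_id`, `branch`, `mechanism`
#'   (`dna_duplication`, `retroposition`, `de_novo` or `unclassified`),
#'   `parent_gene_id`, `parent_cds_exons`, `child_cds_exons`,
#'   `parent_identity`, `outgroup_noncoding`.
#' @export
classify_mechanisms <- function(ages, gm, genome, species_chains,
                                query_models, ladder, lineage_min = 2L,
                                noncoding_min = 0.05, score_floor = 50,
                                min_coverage = 0.3,
                                external_homology = NULL) {
  if (!all(c("branch", "excluded") %in% names(ages))) {
    stop("missing age calls: run assign_branch/apply_filters first")
  }
  new_genes <- ages[!ages$excluded & ages$branch >= lineage_min, ,
                    drop = FALSE]
  prots <- proteome(gm, genome)
  nexon <- cds_exon_counts(gm)
  ex <- gm$features[gm$features$type == "exon", , drop = FALSE]

  rows <- lapply(seq_len(nrow(new_genes)), function(i) {
    gid <- new_genes$gene_id[i]
    br <- new_genes$branch[i]
    par <- if (gid %in% names(prots))
      find_parent(gid, prots, score_floor, min_coverage) else NULL
    child_n <- unname(nexon[gid])
    if (!is.null(par)) {
      parent_n <- unname(nexon[par$parent_id])
      mech <- if (parent_n >= 2L && child_n == 1L) "retroposition"
      else "dna_duplication"
      return(data.frame(gene_id = gid, branch = br, mechanism = mech,
                        parent_gene_id = par$parent_id,
                        parent_cds_exons = parent_n,
                        child_cds_exons = child_n,
                        parent_identity = round(par$identity, 1),
                        outgroup_noncoding = NA,
                        stringsAsFactors = FALSE))
    }
    ## no paralog: look for non-coding homology in pre-origination species
    pre_species <- unlist(ladder$splits$clade[seq_len(min(br, nrow(ladder$splits)))])
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    gr <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end))
    noncoding <- FALSE
    if (!gid %in% external_homology) {
      for (sp in intersect(pre_species, names(species_chains))) {
        cov <- coverage_fraction(gr, species_chains[[sp]])
        if (max(cov) < noncoding_min) next
        if (!overlaps_annotated_gene(gr, species_chains[[sp]],
                                     query_models[[sp]])) {
          noncoding <- TRUE
          break
        }
      }
    }
    data.frame(gene_id = gid, branch = br,
               mechanism = if (noncoding) "de_novo" else "unclassified",
               parent_gene_id = NA_character_, parent_cds_exons = NA,
               child_cds_exons = child_n, parent_identity = NA,
               outgroup_noncoding = noncoding, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    gene_id = character(0), branch = integer(0), mechanism = character(0),
    parent_gene_id = character(0), parent_cds_exons = integer(0),
    child_cds_exons = integer(0), parent_identity = numeric(0),
    outgroup_noncoding = logical(0))
  rownames(out) <- NULL
  out
}

## Map focal intervals through the gap-free blocks of reciprocal-best
## chains to query coordinates.
map_to_query <- function(gr, chains) {
  rb_id <- chains$chains$chain_id[chains$chains$reciprocal_best]
  strand_of <- stats::setNames(chains$chains$q_strand,
                               chains$chains$chain_id)
  bl <- chains$blocks[chains$blocks$chain_id %in% rb_id, , drop = FALSE]
  if (nrow(bl) == 0L) return(GenomicRanges::GRanges())
  gr_b <- GenomicRanges::GRanges(bl$t_chrom,
                                 IRanges::IRanges(bl$t_start, bl$t_end))
  hits <- GenomicRanges::findOverlaps(gr, gr_b)
  if (length(hits) == 0L) return(GenomicRanges::GRanges())
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  out <- lapply(seq_along(qh), function(h) {
    b <- bl[sh[h], ]
    a <- max(GenomicRanges::start(gr)[qh[h]], b$t_start)
    z <- min(GenomicRanges::end(gr)[qh[h]], b$t_end)
    if (strand_of[[as.character(b$chain_id)]] == "+") {
      GenomicRanges::GRanges(b$q_chrom, IRanges::IRanges(
        b$q_start + (a - b$t_start), b$q_start + (z - b$t_start)))
    } else {
      GenomicRanges::GRanges(b$q_chrom, IRanges::IRanges(
        b$q_end - (z - b$t_start), b$q_end - (a - b$t_start)))
    }
  })
  suppressWarnings(do.call(c, out))
}

## does the homologous location of `gr` (focal intervals) in the query
## species overlap an annotated gene there?
overlaps_annotated_gene <- function(gr, chains, qm) {
  if (is.null(qm)) return(FALSE)
  q_gr <- map_to_query(gr, chains)
  if (length(q_gr) == 0L) return(FALSE)
  qex <- qm$features[qm$features$type == "exon", , drop = FALSE]
  if (nrow(qex) == 0L) return(FALSE)
  q_ann <- GenomicRanges::GRanges(qex$chrom,
                                  IRanges::IRanges(qex$start, qex$end))
  length(GenomicRanges::findOverlaps(q_gr, q_ann)) > 0L
}

#' Per-mechanism counts and percentages
#'
#' @param calls data.frame from [classify_mechanisms].
#' @return data.frame with `mechanism`, `n`, `pct` (percent of classified
#'   genes, via [proportion]); unclassified genes are reported but not
#'   included in the percentage base.
#' @export
partition_summary <- function(calls) {
  mechs <- c("dna_duplication", "retroposition", "de_novo")
  n <- vapply(mechs, function(m) sum(calls$mechanism == m), 0L)
  n_unc <- sum(calls$mechanism == "unclassified")
  total <- sum(n)
  pct <- if (total > 0) vapply(n, proportion, 0, whole = total)
  else rep(0, length(n))
  rbind(data.frame(mechanism = mechs, n = unname(n), pct = unname(pct)),
        data.frame(mechanism = "unclassified", n = n_unc, pct = NA))
}
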