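#' Per-exon syntenic presence of focal genes in query species
#'
#' For every exon of every gene, the fraction of bases covered by
#' reciprocal-best chain blocks is computed per query species; an exon is
#' present in a species when its coverage reaches `threshold`, and a gene
#' is present when any of its exons is (the oldest-exon rule is applied at
#' branch assignment).
#'
#' @param gm focal [gene_models].
#' @param species_chains named list (one entry per query species) of
#'   netted `alignment_chains` (see [reciprocal_best_net]).
#' @param threshold exon coverage fraction required for presence
#'   (default 0.5).
#' @return data.frame with one row per gene x exon x species: `gene_id`,
#'   `exon_id`, `species`, `coverage`, `present`.
#' @export
call_presence <- function(gm, species_chains, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  ex <- gm$features[gm$features$type == "exon", , drop = FALSE]
  ## unique exon intervals per gene (transcripts may share exons)
  ex <- unique(ex[, c("gene_id", "chrom", "start", "end")])
  if (nrow(ex) == 0L) stop("gene set has no exons")
  n_ex <- table(gm$genes$gene_id %in% ex$gene_id)
  missing <- setdiff(gm$genes$gene_id, ex$gene_id)
  if (length(missing)) {
    stop("gene(s) with zero exons: ", paste(missing, collapse = ", "))
  }
  ex <- ex[order(ex$gene_id, ex$start), ]
  ex$exon_id <- stats::ave(seq_len(nrow(ex)), ex$gene_id,
                           FUN = seq_along)
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  out <- lapply(names(species_chains), function(sp) {
    cov <- coverage_fraction(gr, species_chains[[sp]])
    data.frame(gene_id = ex$gene_id, exon_id = ex$exon_id, species = sp,
               coverage = cov, present = cov >= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign origination branches from presence profiles (oldest-exon rule)
#'
#' Each exon is dated by Dollo parsimony (see [dollo_branch]) from the
#' species where it is present; the gene's branch is the minimum (oldest)
#' over its exons.  The focal species is present by construction for every
#' annotated focal gene.
#'
#' @param profile data.frame from [call_presence].
#' @param ladder a [species_ladder].
#' @return data.frame with `gene_id`, `branch`, `excluded` (FALSE),
#'   `exclusion_reason` ("none"); filters are applied separately by
#'   [apply_filters].
#' @export
assign_branch <- function(profile, ladder) {
  if (!all(setdiff(ladder$taxa, ladder$focal) %in% profile$species)) {
    stop("presence profile does not cover all ladder taxa")
  }
  key <- paste(profile$gene_id, profile$exon_id)
  branches <- vapply(split(profile, key), function(d) {
    pres <- stats::setNames(c(d$present, TRUE), c(d$species, ladder$focal))
    dollo_branch(pres, ladder)
  }, 0L)
  gene_of <- vapply(split(profile$gene_id, key), `[`, "", 1L)
  gb <- tapply(branches, gene_of, min)
  data.frame(gene_id = names(gb), branch = as.integer(gb),
             excluded = FALSE, exclusion_reason = "none",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the repeat-overlap and placement exclusion filters
#'
#' A gene is excluded when more than `repeat_max` (strictly) of its exonic
#' bases overlap repeat regions, or when it is not located on a placed
#' chromosome.  The repeat fraction is computed over the union of the
#' gene's exons, since ages derive from exons.
#'
#' @param calls data.frame from [assign_branch].
#' @param gm focal [gene_models].
#' @param repeats [GenomicRanges::GRanges] of merged repeat intervals.
#' @param repeat_max repeat-overlap fraction above which a gene is
#'   excluded (default 0.70, strict inequality).
#' @return `calls` with `excluded` and `exclusion_reason`
#'   (`repeat_overlap`, `unplaced` or `none`) filled in.
#' @export
apply_filters <- function(calls, gm, repeats, repeat_max = 0.70) {
  ex <- gm$features[gm$features$type == "exon", , drop = FALSE]
  fr <- vapply(calls$gene_id, function(g) {
    e <- ex[ex$gene_id == g, , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      e$chrom, IRanges::IRanges(e$start, e$end)))
    tot <- sum(GenomicRanges::width(gr))
    ov <- suppressWarnings(GenomicRanges::intersect(gr, repeats))
    sum(GenomicRanges::width(ov)) / tot
  }, 0)
  placed <- stats::setNames(gm$genes$placed, gm$genes$gene_id)[calls$gene_id]
  calls$exclusion_reason <- ifelse(!placed, "unplaced",
                                   ifelse(fr > repeat_max, "repeat_overlap",
                                          "none"))
  calls$excluded <- calls$exclusion_reason != "none"
  calls$repeat_fraction <- unname(fr)
  calls
}

#' New-gene emergence rate
#'
#' @param n_genes number of genes assigned to the branch (or lineage).
#' @param duration branch (or lineage) duration in Myr.
#' @return genes per Myr, rounded to 1 decimal.
#' @export
emergence_rate <- function(n_genes, duration) {
  if (duration <= 0) stop("duration must be positive")
  round(n_genes / duration, 1)
}

#' Percentage of a count within a total
#'
#' @param part,whole counts with `0 <= part <= whole`, `whole > 0`.
#' @return `100 * part / whole`, rounded to 1 decimal.
#' @export
proportion <- function(part, whole) {
  if (whole <= 0) stop("whole must be positive")
  if (part < 0 || part > whole) stop("part must be within [0, whole]")
  round(100 * part / whole, 1)
}

#' Per-branch summary of age calls
#'
#' @param calls filtered age calls (see [apply_filters]); excluded genes
#'   are ignored.
#' @param ladder a [species_ladder].
#' @param lineage_min first branch counted as lineage-specific
#'   (default 2).
#' @return list with `per_branch` (data.frame: branch, n, duration,
#'   rate), `n_total`, `n_lineage_specific`, `lineage_rate`,
#'   `terminal_rate`, `pct_lineage_specific`.
#' @export
branch_summary <- function(calls, ladder, lineage_min = 2L) {
  ok <- calls[!calls$excluded, , drop = FALSE]
  B <- ladder$n_branches
  n <- vapply(0:B, function(b) sum(ok$branch == b), 0L)
  dur <- ladder$branch_duration
  per_branch <- data.frame(branch = 0:B, n = n, duration = dur,
                           rate = ifelse(is.na(dur), NA,
                                         round(n / dur, 1)))
  n_ls <- sum(n[(lineage_min + 1L):(B + 1L)])
  lineage_age <- ladder$splits$age[lineage_min]
  list(per_branch = per_branch, n_total = nrow(ok),
       n_lineage_specific = n_ls,
       terminal_rate = emergence_rate(n[B + 1L], dur[B + 1L]),
       lineage_rate = emergence_rate(n_ls, lineage_age),
       pct_lineage_specific = proportion(n_ls, nrow(ok)))
}
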