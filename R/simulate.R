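## Forward genome-evolution simulator.
##
## Sequences are held as integer vectors (1=A, 2=C, 3=G, 4=T) while
## evolving and converted to DNAStringSet at the boundary.  A simulation
## state bundles the sequences of one lineage with its gene models, per-gene
## selection parameters and repeat intervals; the state is evolved along the
## focal path of the ladder, snapshotted at each split, and the side
## lineages are evolved independently from the snapshots.

NUC <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: an 8-taxon
#' ladder with a 41.8-Myr terminal branch and a 73.7-Myr lineage stem, a
#' ~2 Mb focal genome, and ~40 planted gene-birth events on the
#' lineage-specific branches 2-5.
#'
#' @param seed integer seed driving every stochastic component.
#' @param n_chromosomes,chromosome_length focal genome shape (bp).
#' @param n_ancestral_genes genes present at the sampled root.
#' @param exons_per_gene integer range of exons per ancestral gene.
#' @param cds_codons integer range of CDS length in codons.
#' @param gc intergenic GC content.
#' @param substitution_rate substitutions/site/Myr on neutral sites.
#' @param kappa transition/transversion rate ratio of the HKY-like
#'   substitution kernel.
#' @param omega_ancestral range of per-gene nonsynonymous acceptance
#'   probabilities for ancestral genes.
#' @param indel_rate indels/site/Myr (intergenic and intronic only).
#' @param indel_mean_len,indel_max_len geometric indel length model.
#' @param events data.frame with columns `branch`, `mechanism`, `count`:
#'   planted gene-birth events per focal-path branch.
#' @param dup_omega_constrained,dup_omega_relaxed,frac_dup_constrained
#'   omega assigned to planted duplicates: a fraction gets the constrained
#'   value, the rest the relaxed value.
#' @param de_novo_codons codon-length range of planted de novo genes.
#' @param de_novo_novel_frac fraction of a de novo exon that is novel
#'   (lineage-specific) sequence; the remainder reuses ancestral
#'   intergenic sequence, so pre-origination species retain detectable but
#'   sub-threshold noncoding homology.
#' @param repeat_density fraction of the genome occupied by interspersed
#'   repeats.
#' @param repeat_unit_len,repeat_n_monomers repeat family shape.
#' @param n_unplaced_genes genes placed on an unannotated focal scaffold
#'   (excluded from dating by the placement filter).
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM baseline.
#' @param frac_young_silent fraction of planted (young) genes with no
#'   expression.
#' @param tissues_fpkm,n_reps_fpkm FPKM matrix design.
#' @param tissues_counts,stages,n_reps_counts count matrix design
#'   (left/right x stage x tissue).
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param count_meanlog,count_sdlog log-normal distribution of per-gene
#'   mean counts.
#' @param asym_fold,n_asym_genes,asym_stage,asym_tissue planted left/right
#'   asymmetric expression: fold change applied to the right side for
#'   `n_asym_genes` planted genes at one stage/tissue.
#' @param ladder a [species_ladder]; defaults to [default_ladder()].
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_chromosomes = 2L, chromosome_length = 1e6,
    n_ancestral_genes = 150L, exons_per_gene = c(1L, 5L),
    cds_codons = c(120L, 400L), gc = 0.41,
    substitution_rate = 5e-4, kappa = 2,
    omega_ancestral = c(0.1, 0.4),
    indel_rate = 2e-6, indel_mean_len = 3, indel_max_len = 50L,
    events = default_event_plan(),
    dup_omega_constrained = 0.2, dup_omega_relaxed = 0.8,
    frac_dup_constrained = 0.5,
    de_novo_codons = c(80L, 160L), de_novo_novel_frac = 0.6,
    repeat_density = 0.05, repeat_unit_len = 400L, repeat_n_monomers = 3L,
    n_unplaced_genes = 2L,
    fpkm_meanlog = log(5), fpkm_sdlog = 1.2, frac_young_silent = 0.3,
    tissues_fpkm = c("brain", "liver", "muscle", "gonadM", "gonadF", "eye"),
    n_reps_fpkm = 2L,
    tissues_counts = c("eye", "muscle", "skin"),
    stages = c("Pre", "Pro", "Clim", "Post"), n_reps_counts = 3L,
    nb_dispersion = 0.05, count_meanlog = log(100), count_sdlog = 1,
    asym_fold = 4, n_asym_genes = 10L, asym_stage = "Pro",
    asym_tissue = "muscle",
    ladder = default_ladder()) {
  cfg <- as.list(environment())
  stopifnot(cfg$substitution_rate >= 0, cfg$indel_rate >= 0,
            cfg$repeat_density >= 0, cfg$nb_dispersion >= 0)
  if (!all(cfg$events$branch %in% seq_len(ladder$n_branches))) {
    stop("planted-event branches must be valid focal-lineage branches (1..B)")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Default planted-event plan: ~40 births on the lineage-specific branches
#' @export
default_event_plan <- function() {
  data.frame(
    branch = rep(2:5, times = 3),
    mechanism = rep(c("dna_duplication", "retroposition", "de_novo"),
                    each = 4),
    count = c(4L, 4L, 5L, 6L,   # dna_duplication
              2L, 2L, 2L, 2L,   # retroposition
              2L, 2L, 3L, 3L))  # de_novo
}

int2dna <- function(v) paste(NUC[v], collapse = "")
dna2int <- function(s) match(strsplit(s, "")[[1]], NUC)

random_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p)
}

## random ORF: ATG + sense codons (no stop) + stop codon, as integer vector
random_orf <- function(n_codons) {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  sense <- setdiff(sense, "ATG")
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  stop_c <- sample(c("TAA", "TAG", "TGA"), 1L)
  dna2int(paste0("ATG", paste(body, collapse = ""), stop_c))
}

#' Simulate the ancestral genome and its gene complement
#'
#' Genes are placed left to right with random intergenic gaps; interspersed
#' repeat copies are written into intergenic space.  Each gene is a valid
#' ORF (ATG ... stop, no internal stop) split over 1 or more exons with
#' intronic spacers; all simulated genes are on the + strand.
#'
#' @param config a [simulation_config].
#' @return a simulation state: list with `seqs` (integer-vector list),
#'   `genes`, `features`, `repeats` (per-chromosome interval data.frame).
#' @export
simulate_ancestral_genome <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chromosome_length
  seqs <- lapply(chroms, function(ch) random_seq(L, config$gc))
  names(seqs) <- chroms

  n <- config$n_ancestral_genes
  genes <- features <- NULL
  if (n > 0L) {
    per_chr <- diff(round(seq(0, n, length.out = config$n_chromosomes + 1L)))
    gi <- 0L
    glist <- flist <- list()
    for (ci in seq_along(chroms)) {
      ng <- per_chr[ci]
      if (ng == 0L) next
      ## draw structures first so we can check they fit
      structs <- lapply(seq_len(ng), function(i) {
        nex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
        ncod <- sample(seq(config$cds_codons[1], config$cds_codons[2]), 1L)
        orf <- random_orf(ncod)
        ## split CDS into nex exon chunks (each >= 30 bp where possible)
        len <- length(orf)
        if (nex > 1L) {
          cuts <- sort(sample(seq(30L, len - 30L), nex - 1L))
          sizes <- diff(c(0L, cuts, len))
        } else sizes <- len
        introns <- if (nex > 1L) sample(80:300, nex - 1L, replace = TRUE)
        else integer(0)
        list(orf = orf, sizes = sizes, introns = introns,
             span = len + sum(introns))
      })
      total <- sum(vapply(structs, `[[`, 0, "span"))
      slack <- L - total
      if (slack < (ng + 1L) * 50L) {
        stop("genes cannot be placed without overlap; ",
             "increase chromosome_length or reduce n_ancestral_genes")
      }
      gaps <- stats::rmultinom(1L, slack - (ng + 1L) * 50L, rep(1, ng + 1L))[, 1] + 50L
      pos <- 1L
      for (i in seq_len(ng)) {
        gi <- gi + 1L
        pos <- pos + gaps[i]
        st <- structs[[i]]
        gid <- sprintf("anc%03d", gi)
        exon_start <- pos
        cds_off <- 0L
        for (e in seq_along(st$sizes)) {
          es <- exon_start
          ee <- es + st$sizes[e] - 1L
          seqs[[ci]][es:ee] <- st$orf[(cds_off + 1L):(cds_off + st$sizes[e])]
          flist[[length(flist) + 1L]] <- data.frame(
            gene_id = gid, transcript_id = paste0(gid, ".t1"),
            type = c("exon", "CDS"), chrom = chroms[ci],
            start = es, end = ee, strand = "+")
          cds_off <- cds_off + st$sizes[e]
          if (e < length(st$sizes)) exon_start <- ee + st$introns[e] + 1L
        }
        glist[[length(glist) + 1L]] <- data.frame(
          gene_id = gid, chrom = chroms[ci], strand = "+", placed = TRUE,
          omega = stats::runif(1, config$omega_ancestral[1],
                               config$omega_ancestral[2]))
        pos <- pos + st$span
      }
    }
    genes <- do.call(rbind, glist)
    features <- do.call(rbind, flist)
  } else {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), placed = logical(0),
                        omega = numeric(0))
    features <- data.frame(gene_id = character(0), transcript_id = character(0),
                           type = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0))
  }

  ## interspersed repeats: overwrite intergenic windows with monomer copies
  repeats <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
  if (config$repeat_density > 0) {
    monomers <- lapply(seq_len(config$repeat_n_monomers), function(i)
      random_seq(config$repeat_unit_len, config$gc))
    n_cop <- round(config$repeat_density * L * config$n_chromosomes /
                     config$repeat_unit_len)
    rlist <- list()
    exon_gr <- GenomicRanges::GRanges(
      features$chrom, IRanges::IRanges(features$start, features$end))
    for (i in seq_len(n_cop)) {
      ci <- sample.int(config$n_chromosomes, 1L)
      p <- sample.int(L - config$repeat_unit_len, 1L)
      w <- GenomicRanges::GRanges(chroms[ci],
                                  IRanges::IRanges(p, p + config$repeat_unit_len - 1L))
      if (length(GenomicRanges::findOverlaps(w, exon_gr)) > 0L) next
      m <- monomers[[sample.int(length(monomers), 1L)]]
      seqs[[ci]][p:(p + config$repeat_unit_len - 1L)] <- m
      rlist[[length(rlist) + 1L]] <- data.frame(
        chrom = chroms[ci], start = p, end = p + config$repeat_unit_len - 1L)
    }
    if (length(rlist)) repeats <- do.call(rbind, rlist)
  }
  list(seqs = seqs, genes = genes, features = features, repeats = repeats)
}

## ---- coding maps ----------------------------------------------------------

## per-chromosome lookup vectors for coding positions, plus a matrix of the
## genomic positions of each codon (all simulated genes are + strand)
build_coding_maps <- function(state) {
  f <- state$features[state$features$type == "CDS", , drop = FALSE]
  maps <- list()
  codon_pos <- NULL
  codon_gene <- character(0)
  for (ch in names(state$seqs)) {
    maps[[ch]] <- list(codon_id = integer(length(state$seqs[[ch]])))
  }
  if (nrow(f)) {
    f <- f[order(f$gene_id, f$start), ]
    pos_by_tx <- split(seq_len(nrow(f)), f$transcript_id)
    all_pos <- list(); all_gene <- list()
    for (tid in names(pos_by_tx)) {
      rows <- pos_by_tx[[tid]]
      p <- unlist(lapply(rows, function(r) f$start[r]:f$end[r]))
      if (length(p) %% 3L != 0L) stop("internal error: CDS not multiple of 3")
      all_pos[[tid]] <- matrix(p, ncol = 3L, byrow = TRUE)
      all_gene[[tid]] <- rep(f$gene_id[rows[1]], length(p) / 3L)
    }
    codon_pos <- do.call(rbind, all_pos)
    codon_gene <- unlist(all_gene, use.names = FALSE)
    is_first <- unlist(lapply(all_pos, function(m)
      c(TRUE, rep(FALSE, nrow(m) - 1L))), use.names = FALSE)
    chrom_of_codon <- rep(unlist(lapply(names(pos_by_tx), function(tid)
      f$chrom[pos_by_tx[[tid]][1]])),
      times = vapply(all_pos, nrow, 0L))
    allp <- as.vector(t(codon_pos))
    allk <- rep(seq_len(nrow(codon_pos)), each = 3L)
    allc <- rep(chrom_of_codon, each = 3L)
    for (ch in unique(allc)) {
      sel <- allc == ch
      maps[[ch]]$codon_id[allp[sel]] <- allk[sel]
    }
  }
  list(maps = maps, codon_pos = codon_pos, codon_gene = codon_gene,
       is_first = if (!is.null(codon_pos)) is_first else logical(0),
       codon_chrom = if (!is.null(codon_pos)) chrom_of_codon else character(0))
}

## HKY-like proposal: new base given old (kappa-weighted transition)
TRANSITION <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
propose_base <- function(old, kappa) {
  n <- length(old)
  is_ts <- stats::runif(n) < kappa / (kappa + 2)
  new <- ifelse(is_ts, TRANSITION[old], 0L)
  tv <- which(!is_ts)
  if (length(tv)) {
    pick <- stats::runif(length(tv)) < 0.5
    tvs <- matrix(c(2L, 4L, 1L, 3L, 2L, 4L, 1L, 3L), nrow = 4L,
                  byrow = TRUE)  # the two transversion targets per base
    new[tv] <- tvs[cbind(old[tv], 1L + pick)]
  }
  new
}

GC_VEC <- NULL
aa_of <- local({
  tab <- NULL
  function(codon_int) {
    if (is.null(tab)) {
      gcv <- Biostrings::GENETIC_CODE
      tab <<- array("", dim = c(4, 4, 4))
      for (i in 1:4) for (j in 1:4) for (k in 1:4) {
        tab[i, j, k] <<- gcv[[paste0(NUC[i], NUC[j], NUC[k])]]
      }
      tab
    }
    tab[matrix(codon_int, ncol = 3L)]
  }
})

#' Evolve a simulation state along one branch
#'
#' Substitutions arrive as a Poisson process at the configured neutral
#' rate; proposals in coding positions are accepted with probability 1 if
#' synonymous, with the gene's omega if nonsynonymous, and never if they
#' create a stop codon.  Indels (geometric lengths) are restricted to
#' intergenic and intronic sequence; gene, repeat and feature coordinates
#' are remapped after each branch.
#'
#' @param state a simulation state (see [simulate_ancestral_genome]).
#' @param duration branch duration in Myr.
#' @param config a [simulation_config].
#' @return the evolved state.
#' @export
evolve_branch <- function(state, duration, config) {
  if (duration <= 0) return(state)
  cm <- build_coding_maps(state)
  omega_of <- stats::setNames(state$genes$omega, state$genes$gene_id)

  for (ch in names(state$seqs)) {
    L <- length(state$seqs[[ch]])
    nsub <- stats::rpois(1L, L * config$substitution_rate * duration)
    if (nsub > 0L) {
      pos <- sample.int(L, min(nsub, L))
      cid <- cm$maps[[ch]]$codon_id[pos]
      ## noncoding: apply vectorized
      nc <- pos[cid == 0L]
      if (length(nc)) {
        state$seqs[[ch]][nc] <- propose_base(state$seqs[[ch]][nc], config$kappa)
      }
      ## coding: sequential accept/reject
      cpos <- pos[cid != 0L]
      ccid <- cid[cid != 0L]
      if (length(cpos)) {
        sq <- state$seqs[[ch]]
        u_omega <- stats::runif(length(cpos))
        newb <- propose_base(sq[cpos], config$kappa)
        for (ii in seq_along(cpos)) {
          k <- ccid[ii]
          cp <- cm$codon_pos[k, ]
          old_codon <- sq[cp]
          new_codon <- old_codon
          new_codon[match(cpos[ii], cp)] <- newb[ii]
          ## re-propose from the current base (may have changed earlier)
          aa_old <- aa_of(old_codon)
          aa_new <- aa_of(new_codon)
          if (aa_new == "*" && aa_old != "*") next       # no nonsense changes
          if (aa_old == "*" && aa_new != "*") next       # no stop loss
          if (aa_old == "M" && identical(old_codon, dna2int("ATG")) &&
              cm$is_first[k] && aa_new != "M") next      # start conserved
          if (aa_new != aa_old && aa_old != "*") {
            om <- omega_of[[cm$codon_gene[k]]]
            if (u_omega[ii] >= om) next
          }
          sq[cp] <- new_codon
        }
        state$seqs[[ch]] <- sq
      }
    }

    ## indels
    nind <- stats::rpois(1L, L * config$indel_rate * duration)
    if (nind > 0L) {
      exf <- state$features[state$features$type == "exon" &
                              state$features$chrom == ch, , drop = FALSE]
      ex_ir <- IRanges::IRanges(exf$start, exf$end)
      lens <- pmin(stats::rgeom(nind, 1 / config$indel_mean_len) + 1L,
                   config$indel_max_len)
      at <- sort(sample.int(L - max(lens) - 1L, nind))
      is_ins <- stats::runif(nind) < 0.5
      ## drop indels touching exons or each other
      iv <- IRanges::IRanges(at, ifelse(is_ins, at, at + lens - 1L))
      ok <- IRanges::countOverlaps(iv, ex_ir) == 0L
      if (any(ok)) {
        sel <- which(ok)
        keep <- sel[c(TRUE, diff(at[sel]) > max(lens) + 1L)]
        ed <- data.frame(at = at[keep], len = lens[keep],
                         ins = is_ins[keep])
        state <- apply_indels(state, ch, ed, config)
      }
    }
  }
  state$duration_evolved <- (state$duration_evolved %||% 0) + duration
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## apply a set of non-overlapping indels (original coordinates) to one
## chromosome: rebuild the sequence once and remap all annotations
apply_indels <- function(state, ch, ed, config) {
  ed <- ed[order(ed$at), , drop = FALSE]
  sq <- state$seqs[[ch]]
  pieces <- list()
  shift_at <- integer(nrow(ed)); shift_by <- integer(nrow(ed))
  prev <- 1L
  for (i in seq_len(nrow(ed))) {
    if (ed$ins[i]) {
      ## insertion after position at
      pieces[[length(pieces) + 1L]] <- sq[prev:ed$at[i]]
      pieces[[length(pieces) + 1L]] <- random_seq(ed$len[i], config$gc)
      prev <- ed$at[i] + 1L
      shift_at[i] <- ed$at[i]; shift_by[i] <- ed$len[i]
    } else {
      ## deletion of [at, at+len-1]
      if (ed$at[i] > prev) pieces[[length(pieces) + 1L]] <- sq[prev:(ed$at[i] - 1L)]
      prev <- ed$at[i] + ed$len[i]
      shift_at[i] <- ed$at[i]; shift_by[i] <- -ed$len[i]
    }
  }
  pieces[[length(pieces) + 1L]] <- sq[prev:length(sq)]
  state$seqs[[ch]] <- unlist(pieces, use.names = FALSE)

  remap <- function(x) x + cumsum_shift(x, shift_at, shift_by)
  fi <- state$features$chrom == ch
  state$features$start[fi] <- remap(state$features$start[fi])
  state$features$end[fi] <- remap(state$features$end[fi])
  ri <- state$repeats$chrom == ch
  state$repeats$start[ri] <- remap(state$repeats$start[ri])
  state$repeats$end[ri] <- remap(state$repeats$end[ri])
  ## a deletion overlapping a repeat edge can invert the interval; drop those
  bad <- state$repeats$start > state$repeats$end
  if (any(bad)) state$repeats <- state$repeats[!bad, , drop = FALSE]
  state
}

## total coordinate shift affecting original position x:
## insertions at 'a' shift positions > a; deletions at 'a' shift positions >= a+len
cumsum_shift <- function(x, at, by) {
  if (length(at) == 0L) return(rep(0L, length(x)))
  idx <- findInterval(x - 1L, at)   # events with at <= x-1, i.e. strictly before x
  c(0L, cumsum(by))[idx + 1L]
}

## ---- event planting -------------------------------------------------------

## choose an intergenic insertion point (not inside any gene span or repeat)
pick_insertion_point <- function(state, min_margin = 200L) {
  for (try in 1:200) {
    ch <- sample(names(state$seqs), 1L)
    L <- length(state$seqs[[ch]])
    p <- sample.int(L - 2L * min_margin, 1L) + min_margin
    f <- state$features[state$features$chrom == ch, , drop = FALSE]
    spans <- if (nrow(f)) do.call(rbind, lapply(split(f, f$gene_id), function(d)
      c(min(d$start), max(d$end)))) else matrix(0, 0, 2)
    near_gene <- nrow(spans) && any(p >= spans[, 1] - min_margin &
                                      p <= spans[, 2] + min_margin)
    r <- state$repeats[state$repeats$chrom == ch, , drop = FALSE]
    near_rep <- nrow(r) && any(p >= r$start - 10L & p <= r$end + 10L)
    if (!near_gene && !near_rep) return(list(chrom = ch, pos = p))
  }
  stop("could not find an intergenic insertion point")
}

insert_sequence <- function(state, ch, pos, insert, config) {
  ed <- data.frame(at = pos, len = length(insert), ins = TRUE)
  ## splice the specific sequence (apply_indels inserts random sequence)
  sq <- state$seqs[[ch]]
  state$seqs[[ch]] <- c(sq[1:pos], insert, sq[(pos + 1L):length(sq)])
  remap <- function(x) ifelse(x > pos, x + length(insert), x)
  fi <- state$features$chrom == ch
  state$features$start[fi] <- remap(state$features$start[fi])
  state$features$end[fi] <- remap(state$features$end[fi])
  ri <- state$repeats$chrom == ch
  state$repeats$start[ri] <- remap(state$repeats$start[ri])
  state$repeats$end[ri] <- remap(state$repeats$end[ri])
  state
}

#' Plant a gene-birth event in a simulation state
#'
#' `dna_duplication` copies the parent's genomic span (exons and introns)
#' to a new intergenic locus; `retroposition` inserts the parent's spliced
#' CDS as a new single-exon gene (the parent must have at least 2 CDS
#' exons); `de_novo` builds a new single-exon ORF in place over an
#' existing intergenic segment, adding novel sequence for a configured
#' fraction of the exon and removing in-frame stops from the reused
#' ancestral sequence, so that pre-origination species carry homologous
#' non-coding DNA but no ORF.
#'
#' @param state simulation state.
#' @param gene_id identifier for the new gene.
#' @param mechanism one of `dna_duplication`, `retroposition`, `de_novo`.
#' @param branch the focal-path branch being evolved (recorded as truth).
#' @param omega selection parameter of the new gene.
#' @param config a [simulation_config].
#' @param parent_id optional explicit parent gene (sampled if `NULL`).
#' @param parent_pool optional character vector restricting which genes may
#'   be sampled as duplication parents (e.g. ancestral genes only, so that
#'   every planted child has a unique unambiguous parent).
#' @return list `state` (updated) and `truth` (one-row data.frame).
#' @export
plant_event <- function(state, gene_id, mechanism, branch, omega, config,
                        parent_id = NULL, parent_pool = NULL) {
  f <- state$features
  if (mechanism %in% c("dna_duplication", "retroposition")) {
    cds_per_gene <- table(f$gene_id[f$type == "CDS"])
    cand <- names(cds_per_gene)
    if (is.null(parent_id) && !is.null(parent_pool)) {
      cand <- intersect(cand, parent_pool)
      cds_per_gene <- cds_per_gene[cand]
    }
    if (mechanism == "retroposition") cand <- names(cds_per_gene)[cds_per_gene >= 2L]
    if (is.null(parent_id)) {
      if (length(cand) == 0L) stop("no eligible parent gene")
      parent_id <- sample(cand, 1L)
    } else if (mechanism == "retroposition" &&
               cds_per_gene[[parent_id]] < 2L) {
      stop("retroposition requires a multi-exon parent")
    }
    pf <- f[f$gene_id == parent_id, , drop = FALSE]
    pch <- pf$chrom[1]
    ip <- pick_insertion_point(state)
    if (mechanism == "dna_duplication") {
      span <- c(min(pf$start), max(pf$end))
      insert <- state$seqs[[pch]][span[1]:span[2]]
      state <- insert_sequence(state, ip$chrom, ip$pos, insert, config)
      nf <- pf
      nf$gene_id <- gene_id
      nf$transcript_id <- paste0(gene_id, ".t1")
      nf$chrom <- ip$chrom
      nf$start <- pf$start - span[1] + ip$pos + 1L
      nf$end <- pf$end - span[1] + ip$pos + 1L
    } else {
      cds <- pf[pf$type == "CDS", , drop = FALSE]
      cds <- cds[order(cds$start), ]
      insert <- unlist(lapply(seq_len(nrow(cds)), function(i)
        state$seqs[[pch]][cds$start[i]:cds$end[i]]), use.names = FALSE)
      state <- insert_sequence(state, ip$chrom, ip$pos, insert, config)
      nf <- data.frame(gene_id = gene_id,
                       transcript_id = paste0(gene_id, ".t1"),
                       type = c("exon", "CDS"), chrom = ip$chrom,
                       start = ip$pos + 1L,
                       end = ip$pos + length(insert), strand = "+")
    }
    state$features <- rbind(state$features, nf)
    state$genes <- rbind(state$genes, data.frame(
      gene_id = gene_id, chrom = ip$chrom, strand = "+", placed = TRUE,
      omega = omega))
    truth <- data.frame(gene_id = gene_id, true_branch = branch,
                        true_mechanism = mechanism,
                        parent_gene_id = parent_id, true_omega = omega)
  } else if (mechanism == "de_novo") {
    n_cod <- sample(seq(config$de_novo_codons[1], config$de_novo_codons[2]), 1L)
    len <- 3L * n_cod
    anc_len <- round(len * (1 - config$de_novo_novel_frac))
    anc_len <- anc_len - anc_len %% 3L
    nov_len <- len - anc_len
    nov5 <- nov_len %/% 2L; nov5 <- nov5 - (nov5 %% 3L) + 3L  # includes ATG
    nov3 <- len - anc_len - nov5
    stopifnot(nov3 >= 3L)
    ip <- pick_insertion_point(state, min_margin = anc_len + 500L)
    ch <- ip$chrom
    ## reuse the ancestral segment [pos+1, pos+anc_len] as the exon middle
    seg <- state$seqs[[ch]][(ip$pos + 1L):(ip$pos + anc_len)]
    ## remove in-frame stops by editing third positions
    if (anc_len >= 3L) {
      cm <- matrix(seg, ncol = 3L, byrow = TRUE)
      for (k in seq_len(nrow(cm))) {
        while (aa_of(cm[k, ]) == "*") cm[k, 3] <- sample.int(4L, 1L)
      }
      seg <- as.vector(t(cm))
      state$seqs[[ch]][(ip$pos + 1L):(ip$pos + anc_len)] <- seg
    }
    gc_tab <- Biostrings::GENETIC_CODE
    sense <- setdiff(names(gc_tab)[gc_tab != "*"], "ATG")
    five <- dna2int(paste0("ATG", paste(
      sample(sense, nov5 / 3L - 1L, replace = TRUE), collapse = "")))
    three <- dna2int(paste0(
      paste(sample(sense, nov3 / 3L - 1L, replace = TRUE), collapse = ""),
      sample(c("TAA", "TAG", "TGA"), 1L)))
    ## insert novel 3' part first (higher coordinate), then novel 5' part
    state <- insert_sequence(state, ch, ip$pos + anc_len, three, config)
    state <- insert_sequence(state, ch, ip$pos, five, config)
    start <- ip$pos + 1L
    end <- ip$pos + nov5 + anc_len + nov3
    state$features <- rbind(state$features, data.frame(
      gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
      type = c("exon", "CDS"), chrom = ch, start = start, end = end,
      strand = "+"))
    state$genes <- rbind(state$genes, data.frame(
      gene_id = gene_id, chrom = ch, strand = "+", placed = TRUE,
      omega = omega))
    truth <- data.frame(gene_id = gene_id, true_branch = branch,
                        true_mechanism = mechanism,
                        parent_gene_id = NA_character_, true_omega = omega)
  } else stop("unknown mechanism: ", mechanism)
  list(state = state, truth = truth)
}

## ---- full ladder simulation -----------------------------------------------

#' Simulate a full ladder of genomes with planted gene-birth events
#'
#' Evolves an ancestral genome along the focal path of the ladder,
#' snapshotting at each split and evolving the side lineages independently
#' to their tips; events of the configured plan are planted at the start
#' of their branch.  Deterministic for a given config (the config seed is
#' set at entry).
#'
#' @param config a [simulation_config].
#' @return object of class `genome_simulation`: list with `genomes` (named
#'   list of [Biostrings::DNAStringSet]), `models` (named list of
#'   [gene_models]), `repeats` (focal [GenomicRanges::GRanges]),
#'   `chromosomes` (placed focal chromosome names), `truth` (data.frame),
#'   `fpkm`, `counts` (expression matrices), `expr_truth`, `ladder`,
#'   `config`.
#' @export
simulate_genomes <- function(config) {
  set.seed(config$seed)
  ladder <- config$ladder
  anc <- simulate_ancestral_genome(config)
  anc$repeats <- anc$repeats
  truth <- list()

  evolve_lineage <- function(state, duration) {
    evolve_branch(state, duration, config)
  }
  ## evolve one off-path subtree from a snapshot down to its tips
  evolve_clade <- function(state, taxa, split_age) {
    out <- list()
    if (length(taxa) == 1L) {
      out[[taxa]] <- evolve_lineage(state, split_age)
    } else if (length(taxa) == 2L) {
      cherry_age <- min(30, split_age / 2)
      ## cherry node ages come from the ladder tree when available
      tr <- ladder$tree
      mrca <- ape::getMRCA(tr, taxa)
      if (!is.null(mrca)) {
        cherry_age <- unname(ape::branching.times(tr)[as.character(mrca)])
      }
      stem <- evolve_lineage(state, split_age - cherry_age)
      for (tx in taxa) out[[tx]] <- evolve_lineage(stem, cherry_age)
    } else stop("off-path clades larger than 2 are not supported")
    out
  }

  species <- list()
  state <- anc
  ages <- c(ladder$splits$age, 0)
  ev <- config$events
  counters <- list(dna_duplication = 0L, retroposition = 0L, de_novo = 0L)
  short <- c(dna_duplication = "dna", retroposition = "retro",
             de_novo = "denovo")
  for (i in seq_len(nrow(ladder$splits))) {
    ## clade splitting off at this node evolves from the current state
    species <- c(species,
                 evolve_clade(state, ladder$splits$clade[[i]],
                              ladder$splits$age[i]))
    ## plant events of branch i at the start of the branch, then evolve
    evb <- ev[ev$branch == i & ev$count > 0L, , drop = FALSE]
    for (r in seq_len(nrow(evb))) {
      for (j in seq_len(evb$count[r])) {
        mech <- evb$mechanism[r]
        counters[[mech]] <- counters[[mech]] + 1L
        gid <- sprintf("%s_b%d_%02d", short[[mech]], i, counters[[mech]])
        omega <- switch(mech,
          dna_duplication = ,
          retroposition = if (stats::runif(1) < config$frac_dup_constrained)
            config$dup_omega_constrained else config$dup_omega_relaxed,
          de_novo = 1)
        pl <- plant_event(state, gid, mech, i, omega, config,
                          parent_pool = anc$genes$gene_id)
        state <- pl$state
        truth[[length(truth) + 1L]] <- pl$truth
      }
    }
    state <- evolve_lineage(state, ages[i] - ages[i + 1L])
  }
  species[[ladder$focal]] <- state
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), true_branch = integer(0),
               true_mechanism = character(0), parent_gene_id = character(0),
               true_omega = numeric(0))

  ## unplaced focal scaffold with species-specific genes (excluded from
  ## dating by the placement filter)
  chromosomes <- names(species[[ladder$focal]]$seqs)
  if (config$n_unplaced_genes > 0L) {
    fs <- species[[ladder$focal]]
    sc <- "scaffold_1"
    sclen <- 5e4L
    fs$seqs[[sc]] <- random_seq(sclen, config$gc)
    pos <- 1000L
    for (i in seq_len(config$n_unplaced_genes)) {
      orf <- random_orf(150L)
      fs$seqs[[sc]][pos:(pos + length(orf) - 1L)] <- orf
      gid <- sprintf("unpl%02d", i)
      fs$features <- rbind(fs$features, data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".t1"),
        type = c("exon", "CDS"), chrom = sc, start = pos,
        end = pos + length(orf) - 1L, strand = "+"))
      fs$genes <- rbind(fs$genes, data.frame(
        gene_id = gid, chrom = sc, strand = "+", placed = FALSE,
        omega = 1))
      pos <- pos + length(orf) + 2000L
    }
    species[[ladder$focal]] <- fs
  }

  genomes <- lapply(species, function(s) {
    g <- Biostrings::DNAStringSet(vapply(s$seqs, int2dna, ""))
    names(g) <- names(s$seqs)
    g
  })
  models <- lapply(species, function(s) {
    genes <- s$genes
    genes$placed <- genes$chrom %in% chromosomes
    genes$cds_ok <- TRUE
    gene_models(genes[, c("gene_id", "chrom", "strand", "placed", "cds_ok")],
                s$features)
  })
  focal_state <- species[[ladder$focal]]
  repeats <- GenomicRanges::reduce(GenomicRanges::GRanges(
    focal_state$repeats$chrom,
    IRanges::IRanges(focal_state$repeats$start, focal_state$repeats$end)))

  expr <- simulate_expression(models[[ladder$focal]], truth, config)

  structure(list(genomes = genomes, models = models, repeats = repeats,
                 chromosomes = chromosomes, truth = truth,
                 fpkm = expr$fpkm, counts = expr$counts,
                 expr_truth = expr$truth, ladder = ladder, config = config),
            class = "genome_simulation")
}

#' @export
print.genome_simulation <- function(x, ...) {
  cat("genome_simulation:", length(x$genomes), "genomes,",
      nrow(x$models[[x$ladder$focal]]$genes), "focal genes,",
      nrow(x$truth), "planted events\n")
  invisible(x)
}

#' Simulate FPKM and count expression matrices
#'
#' Baseline per-gene abundance is log-normal; a configured fraction of
#' planted (young) genes is silent in every sample.  Counts are negative
#' binomial around per-gene means with the configured dispersion;
#' designated planted genes receive a left/right fold change at one
#' stage/tissue.
#'
#' @param gm focal [gene_models].
#' @param truth planted-event table (see [simulate_genomes]).
#' @param config a [simulation_config].
#' @return list with `fpkm`, `counts` (expression matrices) and `truth`
#'   (data.frame: gene_id, silent, asymmetric).
#' @export
simulate_expression <- function(gm, truth, config) {
  gids <- gm$genes$gene_id
  n <- length(gids)
  young <- gids %in% truth$gene_id
  silent <- young & stats::runif(n) < config$frac_young_silent

  base <- stats::rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog)
  base[silent] <- 0
  tiss <- config$tissues_fpkm
  cols <- as.vector(outer(tiss, seq_len(config$n_reps_fpkm),
                          function(t, r) paste0(t, ".", r)))
  teff <- matrix(stats::rlnorm(n * length(tiss), 0, 0.5), n)
  fpkm <- matrix(0, n, length(cols), dimnames = list(gids, cols))
  for (j in seq_along(cols)) {
    ti <- match(sub("\\..*$", "", cols[j]), tiss)
    fpkm[, j] <- base * teff[, ti] * stats::rlnorm(n, 0, 0.2)
  }
  fpkm <- round(fpkm, 3)

  ## counts: left/right x stage x tissue x replicate
  young_ids <- truth$gene_id[truth$true_branch <= max(2L,
                               config$ladder$n_branches - 1L)]
  young_ids <- setdiff(young_ids, gids[silent])
  asym <- young_ids[sample.int(length(young_ids),
                               min(config$n_asym_genes, length(young_ids)))]
  mu <- stats::rlnorm(n, config$count_meanlog, config$count_sdlog)
  mu[silent] <- 0
  combos <- expand.grid(rep = seq_len(config$n_reps_counts),
                        side = c("L", "R"), stage = config$stages,
                        tissue = config$tissues_counts,
                        stringsAsFactors = FALSE)
  cn <- with(combos, paste(tissue, side, stage, rep, sep = "."))
  cnt <- matrix(0L, n, nrow(combos), dimnames = list(gids, cn))
  for (j in seq_len(nrow(combos))) {
    m <- mu
    if (combos$side[j] == "R" && combos$stage[j] == config$asym_stage &&
        combos$tissue[j] == config$asym_tissue) {
      m[gids %in% asym] <- m[gids %in% asym] * config$asym_fold
    }
    pos <- m > 0
    cnt[pos, j] <- stats::rnbinom(sum(pos), mu = m[pos],
                                  size = 1 / config$nb_dispersion)
  }
  list(fpkm = expression_matrix(fpkm, "fpkm"),
       counts = expression_matrix(cnt, "counts"),
       truth = data.frame(gene_id = gids, silent = silent,
                          asymmetric = gids %in% asym))
}

#' Write all simulation outputs to a directory
#'
#' Emits `<species>.fa` and `<species>.gff3` per species,
#' `focal.repeats.bed`, `fpkm.tsv`, `counts.tsv` and `truth.tsv`.
#'
#' @param sim a `genome_simulation`.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes)) {
    write_genome(sim$genomes[[sp]], file.path(dir, paste0(sp, ".fa")))
    write_gene_models(sim$models[[sp]], file.path(dir, paste0(sp, ".gff3")))
  }
  write_repeats(sim$repeats, file.path(dir, "focal.repeats.bed"))
  write_expression_matrix(sim$fpkm, file.path(dir, "fpkm.tsv"))
  write_expression_matrix(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
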