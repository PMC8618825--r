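#' Alignment parameter sets
#'
#' Scoring defaults: match +1, mismatch -1, gap open 4 / extend 1, x-drop
#' 20, minimum chain score 100, seed length `k = 12`, seed occurrence
#' ceiling 10.  Presets loosen seeding and extension with query divergence
#' (`near` < `mid` < `far`), standing in for the per-divergence parameter
#' sets genome browsers use for pairwise genome alignment.
#'
#' @param preset `"near"`, `"mid"` or `"far"`.
#' @param ... named overrides of individual parameters.
#' @return named list of parameters.
#' @export
align_params <- function(preset = c("near", "mid", "far"), ...) {
  preset <- match.arg(preset)
  p <- list(k = 12L, match = 1L, mismatch = 1L, gap_open = 4L,
            gap_extend = 1L, xdrop = 20L, min_chain_score = 100L,
            max_occ = 10L)
  if (preset == "mid") { p$k <- 11L; p$xdrop <- 25L }
  if (preset == "far") { p$k <- 10L; p$xdrop <- 30L }
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Build a k-mer seed index of a genome
#'
#' Maps every k-mer not containing `N`, and not occurring more than
#' `max_occ` times, to its 1-based start positions.  This is the seeding
#' stage of the aligner exposed for inspection; [align_genomes] uses an
#' equivalent internal index.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param k seed length (`k >= 8`).
#' @param max_occ occurrence ceiling; more frequent k-mers are masked.
#' @return nested list: `index[[chrom]][[kmer]]` = integer positions.
#' @export
build_seed_index <- function(genome, k, max_occ = 10L) {
  if (k < 8L) stop("k must be >= 8")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  out <- lapply(as.character(genome), function(s) {
    n <- nchar(s)
    if (n < k) return(list())
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    idx <- split(starts[keep], kmers[keep])
    idx[lengths(idx) <= max_occ]
  })
  names(out) <- names(genome)
  out
}

#' Pairwise whole-genome alignment (seed-and-extend + colinear chaining)
#'
#' Aligns every query sequence against every target chromosome on both
#' strands: exact k-mer seeds (soft-masked regions of the target are
#' excluded from seeding but not extension), ungapped x-drop extension,
#' and sparse colinear chaining with affine gap costs.  The target
#' ("focal") strand is always `+`.
#'
#' @param target,query named [Biostrings::DNAStringSet] genomes.
#' @param params from [align_params].
#' @param target_mask optional [GenomicRanges::GRanges] of repeat intervals
#'   on the target excluded from seeding (soft-masking).
#' @return an object of class `alignment_chains`: list with `chains`
#'   (data.frame: `chain_id`, `t_chrom`, `t_start`, `t_end`, `q_chrom`,
#'   `q_start`, `q_end`, `q_strand`, `score`, `reciprocal_best`), `blocks`
#'   (data.frame of gap-free block pairs per chain), all coordinates
#'   1-based closed, query block coordinates given on the + strand of the
#'   query.
#' @export
align_genomes <- function(target, query, params = align_params(),
                          target_mask = NULL) {
  if (is.character(target)) target <- Biostrings::DNAStringSet(target)
  if (is.character(query)) query <- Biostrings::DNAStringSet(query)
  chains <- list(); blocks <- list(); cid <- 0L
  for (tc in names(target)) {
    tseq <- as.character(target[[tc]])
    ms <- me <- integer(0)
    if (!is.null(target_mask)) {
      mm <- target_mask[GenomicRanges::seqnames(target_mask) == tc]
      ms <- GenomicRanges::start(mm) - 1L
      me <- GenomicRanges::end(mm) - 1L
    }
    for (qc in names(query)) {
      qfwd <- as.character(query[[qc]])
      qlen <- nchar(qfwd)
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") qfwd else
          as.character(Biostrings::reverseComplement(query[[qc]]))
        res <- .align_strand_cpp(tseq, qs, params$k, params$match,
                                 params$mismatch, params$gap_open,
                                 params$gap_extend, params$xdrop,
                                 params$min_chain_score, params$max_occ,
                                 ms, me)
        nres <- length(res$ts)
        if (nres == 0L) next
        ids <- cid + seq_len(nres)
        cid <- cid + nres
        if (strand == "+") {
          q_start <- res$qs + 1L; q_end <- res$qe + 1L
        } else {
          q_start <- qlen - res$qe; q_end <- qlen - res$qs
        }
        chains[[length(chains) + 1L]] <- data.frame(
          chain_id = ids, t_chrom = tc, t_start = res$ts + 1L,
          t_end = res$te + 1L, q_chrom = qc, q_start = q_start,
          q_end = q_end, q_strand = strand, score = res$score,
          reciprocal_best = FALSE, stringsAsFactors = FALSE)
        bm <- do.call(rbind, res$blocks)
        nb <- vapply(res$blocks, nrow, 0L)
        b_ts <- bm[, 1] + 1L; b_te <- bm[, 2] + 1L
        if (strand == "+") {
          b_qs <- bm[, 3] + 1L; b_qe <- bm[, 4] + 1L
        } else {
          b_qs <- qlen - bm[, 4]; b_qe <- qlen - bm[, 3]
        }
        blocks[[length(blocks) + 1L]] <- data.frame(
          chain_id = rep(ids, nb), t_chrom = tc, t_start = b_ts,
          t_end = b_te, q_chrom = qc, q_start = b_qs, q_end = b_qe,
          stringsAsFactors = FALSE)
      }
    }
  }
  ch <- if (length(chains)) do.call(rbind, chains) else
    data.frame(chain_id = integer(0), t_chrom = character(0),
               t_start = integer(0), t_end = integer(0),
               q_chrom = character(0), q_start = integer(0),
               q_end = integer(0), q_strand = character(0),
               score = numeric(0), reciprocal_best = logical(0))
  bl <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chain_id = integer(0), t_chrom = character(0),
               t_start = integer(0), t_end = integer(0),
               q_chrom = character(0), q_start = integer(0),
               q_end = integer(0))
  obj <- structure(list(chains = ch, blocks = bl),
                   class = "alignment_chains")
  obj <- merge_colinear_chains(obj, params)
  obj$chains <- obj$chains[order(obj$chains$t_chrom, obj$chains$t_start), ,
                           drop = FALSE]
  rownames(obj$chains) <- rownames(obj$blocks) <- NULL
  obj
}

## Second-level chaining: local chains that are colinear on the same
## chromosome pair and strand are merged into one chain (with the same
## affine gap cost), so that both alignment directions produce comparable
## long-range chains regardless of how the anchor-level chaining
## fragmented.
merge_colinear_chains <- function(obj, params, max_gap = 1e5,
                                  max_shift = 2e4, max_overlap = 200L) {
  ch <- obj$chains
  if (nrow(ch) < 2L) return(obj)
  ch$qs_eff <- ifelse(ch$q_strand == "+", ch$q_start, -ch$q_end)
  ch$qe_eff <- ifelse(ch$q_strand == "+", ch$q_end, -ch$q_start)
  grp <- paste(ch$t_chrom, ch$q_chrom, ch$q_strand)
  blocks_by_chain <- split(seq_len(nrow(obj$blocks)), obj$blocks$chain_id)
  new_chains <- list(); new_blocks <- list(); nid <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    d <- ch[idx, , drop = FALSE]
    o <- order(d$t_start, d$qs_eff)
    d <- d[o, , drop = FALSE]
    n <- nrow(d)
    ## hoist columns: the DP below is the hot path
    v_ts <- d$t_start; v_te <- d$t_end
    v_qs <- d$qs_eff; v_qe <- d$qe_eff; v_sc <- d$score
    dp <- v_sc; pred <- rep(NA_integer_, n); link_cost <- numeric(n)
    for (i in seq_len(n)) {
      for (j in rev(seq_len(i - 1L))) {
        if (v_ts[i] - v_ts[j] > 2 * max_gap) break
        dt <- v_ts[i] - v_te[j] - 1L
        dq <- v_qs[i] - v_qe[j] - 1L
        if (dt < -max_overlap || dq < -max_overlap) next
        if (dt > max_gap || dq > max_gap) next
        gap <- abs(dt - dq)
        if (gap > max_shift) next
        cost <- (gap > 0) * (params$gap_open + params$gap_extend * gap) +
          params$match * max(0, -dt, -dq)
        cand <- dp[j] + v_sc[i] - cost
        if (cand > dp[i]) { dp[i] <- cand; pred[i] <- j; link_cost[i] <- cost }
      }
    }
    ## block coordinates as an integer matrix for this group
    bidx <- unlist(blocks_by_chain[as.character(d$chain_id)],
                   use.names = FALSE)
    bmat <- cbind(ts = obj$blocks$t_start[bidx],
                  te = obj$blocks$t_end[bidx],
                  qs = obj$blocks$q_start[bidx],
                  qe = obj$blocks$q_end[bidx])
    bl_of <- split(seq_len(nrow(bmat)),
                   factor(obj$blocks$chain_id[bidx],
                          levels = d$chain_id))
    plus <- d$q_strand[1] == "+"

    used <- logical(n)
    g_ids <- integer(0); g_sc <- numeric(0)
    g_blocks <- list()
    for (i in order(-dp)) {
      if (used[i]) next
      path <- integer(0); cur <- i
      while (!is.na(cur) && !used[cur]) { path <- c(cur, path); cur <- pred[cur] }
      used[path] <- TRUE
      nid <- nid + 1L
      sc <- sum(v_sc[path]) - sum(link_cost[path[-1L]])
      bl <- bmat[unlist(bl_of[path], use.names = FALSE), , drop = FALSE]
      bl <- bl[order(bl[, "ts"]), , drop = FALSE]
      ## trim any residual block overlap on either genome
      if (nrow(bl) > 1L) {
        qs_eff <- if (plus) bl[, "qs"] else -bl[, "qe"]
        qe_eff <- if (plus) bl[, "qe"] else -bl[, "qs"]
        keep <- rep(TRUE, nrow(bl))
        pt <- bl[1, "te"]; pq <- qe_eff[1]
        for (b in 2:nrow(bl)) {
          trim <- max(pt - bl[b, "ts"] + 1L, pq - qs_eff[b] + 1L, 0L)
          if (trim > 0L) {
            if (bl[b, "ts"] + trim > bl[b, "te"]) { keep[b] <- FALSE; next }
            bl[b, "ts"] <- bl[b, "ts"] + trim
            if (plus) bl[b, "qs"] <- bl[b, "qs"] + trim
            else bl[b, "qe"] <- bl[b, "qe"] - trim
            qs_eff[b] <- qs_eff[b] + trim
          }
          pt <- bl[b, "te"]; pq <- qe_eff[b]
        }
        bl <- bl[keep, , drop = FALSE]
      }
      g_ids <- c(g_ids, nid); g_sc <- c(g_sc, sc)
      g_blocks[[length(g_blocks) + 1L]] <- bl
    }
    nb <- vapply(g_blocks, nrow, 0L)
    ball <- do.call(rbind, g_blocks)
    new_blocks[[length(new_blocks) + 1L]] <- data.frame(
      chain_id = rep(g_ids, nb), t_chrom = d$t_chrom[1],
      t_start = ball[, "ts"], t_end = ball[, "te"],
      q_chrom = d$q_chrom[1], q_start = ball[, "qs"],
      q_end = ball[, "qe"], stringsAsFactors = FALSE)
    new_chains[[length(new_chains) + 1L]] <- data.frame(
      chain_id = g_ids, t_chrom = d$t_chrom[1],
      t_start = vapply(g_blocks, function(b) min(b[, "ts"]), 0L),
      t_end = vapply(g_blocks, function(b) max(b[, "te"]), 0L),
      q_chrom = d$q_chrom[1],
      q_start = vapply(g_blocks, function(b) min(b[, "qs"]), 0L),
      q_end = vapply(g_blocks, function(b) max(b[, "qe"]), 0L),
      q_strand = d$q_strand[1], score = g_sc,
      reciprocal_best = FALSE, stringsAsFactors = FALSE)
  }
  structure(list(chains = do.call(rbind, new_chains),
                 blocks = do.call(rbind, new_blocks)),
            class = "alignment_chains")
}

#' @export
print.alignment_chains <- function(x, ...) {
  cat("alignment_chains:", nrow(x$chains), "chains,",
      nrow(x$blocks), "blocks,", sum(x$chains$reciprocal_best),
      "reciprocal-best\n")
  invisible(x)
}

chain_rank <- function(ch) {
  order(order(-ch$score, ch$t_chrom, ch$t_start, ch$q_chrom, ch$q_start,
              ch$chain_id))
}

#' Reciprocal-best netting of two alignment directions
#'
#' A chain of the focal-to-query direction is flagged reciprocal-best iff
#' (i) it is the best-scoring chain over its focal interval, and (ii) the
#' best query-to-focal chain over its query interval maps back to the same
#' focal interval with at least 50% mutual overlap.  Ties are broken by
#' (score, focal coordinate, query coordinate) lexicographically.  Flagged
#' chains are then pruned greedily so that every focal base is covered by
#' at most one reciprocal-best chain.
#'
#' @param f2q `alignment_chains` with the focal genome as target.
#' @param q2f `alignment_chains` of the reverse direction (same scoring).
#' @param min_mutual minimum mutual overlap fraction (default 0.5).
#' @return `f2q` with `reciprocal_best` set.
#' @export
reciprocal_best_net <- function(f2q, q2f, min_mutual = 0.5) {
  cf <- f2q$chains
  cq <- q2f$chains
  if (nrow(cf) == 0L || nrow(cq) == 0L) {
    if (nrow(cf)) {
      cf$reciprocal_best <- FALSE
      f2q$chains <- cf
    }
    return(f2q)
  }
  cf$reciprocal_best <- FALSE
  rank_f <- chain_rank(cf)
  rank_q <- chain_rank(cq)

  gr_f <- GenomicRanges::GRanges(cf$t_chrom,
                                 IRanges::IRanges(cf$t_start, cf$t_end))
  ## (i) best over own focal interval
  hits <- GenomicRanges::findOverlaps(gr_f, gr_f)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  beaten <- unique(qh[rank_f[sh] < rank_f[qh]])
  best_focal <- !(seq_len(nrow(cf)) %in% beaten)

  ## (ii) reciprocity via the best q2f chain over the query interval
  gr_fq <- GenomicRanges::GRanges(cf$q_chrom,
                                  IRanges::IRanges(cf$q_start, cf$q_end))
  gr_qt <- GenomicRanges::GRanges(cq$t_chrom,
                                  IRanges::IRanges(cq$t_start, cq$t_end))
  hits2 <- GenomicRanges::findOverlaps(gr_fq, gr_qt)
  qh2 <- S4Vectors::queryHits(hits2); sh2 <- S4Vectors::subjectHits(hits2)
  flag <- logical(nrow(cf))
  if (length(qh2)) {
    best_back <- tapply(sh2, qh2, function(js) js[which.min(rank_q[js])])
    for (i in which(best_focal)) {
      j <- best_back[[as.character(i)]]
      if (is.null(j)) next
      if (cq$q_chrom[j] != cf$t_chrom[i]) next
      ov <- min(cq$q_end[j], cf$t_end[i]) - max(cq$q_start[j], cf$t_start[i]) + 1L
      if (ov <= 0L) next
      wf <- cf$t_end[i] - cf$t_start[i] + 1L
      wq <- cq$q_end[j] - cq$q_start[j] + 1L
      if (ov >= min_mutual * wf && ov >= min_mutual * wq) flag[i] <- TRUE
    }
  }

  ## prune: at most one reciprocal-best chain per focal base
  keep <- logical(nrow(cf))
  cand <- which(flag)
  cand <- cand[order(rank_f[cand])]
  cov <- GenomicRanges::GRanges()
  for (i in cand) {
    g <- gr_f[i]
    if (length(GenomicRanges::findOverlaps(g, cov)) == 0L) {
      keep[i] <- TRUE
      cov <- suppressWarnings(c(cov, g))
    }
  }
  cf$reciprocal_best <- keep
  f2q$chains <- cf
  f2q
}

#' Fraction of each interval covered by reciprocal-best chain blocks
#'
#' @param intervals [GenomicRanges::GRanges] on the focal genome.
#' @param chains an `alignment_chains` with `reciprocal_best` flags set.
#' @param chromosomes optional character vector of valid focal chromosome
#'   names; intervals on other sequences raise an error.
#' @return numeric vector in `[0, 1]`, one fraction per interval.
#' @export
coverage_fraction <- function(intervals, chains, chromosomes = NULL) {
  if (!is.null(chromosomes)) {
    bad <- !as.character(GenomicRanges::seqnames(intervals)) %in% chromosomes
    if (any(bad)) {
      stop("interval(s) on unknown chromosome: ", paste(unique(
        as.character(GenomicRanges::seqnames(intervals))[bad]),
        collapse = ", "))
    }
  }
  rb <- chains$chains$chain_id[chains$chains$reciprocal_best]
  bl <- chains$blocks[chains$blocks$chain_id %in% rb, , drop = FALSE]
  if (nrow(bl) == 0L) return(rep(0, length(intervals)))
  gr_b <- GenomicRanges::reduce(GenomicRanges::GRanges(
    bl$t_chrom, IRanges::IRanges(bl$t_start, bl$t_end)))
  ov <- GenomicRanges::findOverlaps(intervals, gr_b)
  w <- rep(0, length(intervals))
  if (length(ov)) {
    pi_ <- GenomicRanges::pintersect(intervals[S4Vectors::queryHits(ov)],
                                     gr_b[S4Vectors::subjectHits(ov)])
    ww <- tapply(GenomicRanges::width(pi_), S4Vectors::queryHits(ov), sum)
    w[as.integer(names(ww))] <- ww
  }
  pmin(w / GenomicRanges::width(intervals), 1)
}

#' Write alignment chains to a tab-separated block file
#'
#' One row per chain (PSL-like): focal chromosome/start/end, query
#' sequence/start/end/strand, score, reciprocal-best flag, and the
#' gap-free blocks packed as comma-separated `t_starts`, `q_starts`,
#' `sizes`.
#'
#' @param chains an `alignment_chains`.
#' @param path output file.
#' @export
write_chains <- function(chains, path) {
  ch <- chains$chains
  bl <- split(chains$blocks, chains$blocks$chain_id)
  pack <- function(id, col) {
    b <- bl[[as.character(id)]]
    paste(b[[col]], collapse = ",")
  }
  ch$block_t_starts <- vapply(ch$chain_id, pack, "", col = "t_start")
  ch$block_q_starts <- vapply(ch$chain_id, pack, "", col = "q_start")
  ch$block_sizes <- vapply(ch$chain_id, function(id) {
    b <- bl[[as.character(id)]]
    paste(b$t_end - b$t_start + 1L, collapse = ",")
  }, "")
  utils::write.table(ch, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read alignment chains from a tab-separated block file
#' @param path file written by [write_chains].
#' @return an `alignment_chains`.
#' @export
read_chains <- function(path) {
  ch <- utils::read.delim(path, stringsAsFactors = FALSE)
  blocks <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    ts <- as.integer(strsplit(ch$block_t_starts[i], ",")[[1]])
    qs <- as.integer(strsplit(ch$block_q_starts[i], ",")[[1]])
    sz <- as.integer(strsplit(ch$block_sizes[i], ",")[[1]])
    data.frame(chain_id = ch$chain_id[i], t_chrom = ch$t_chrom[i],
               t_start = ts, t_end = ts + sz - 1L,
               q_chrom = ch$q_chrom[i], q_start = qs,
               q_end = qs + sz - 1L, stringsAsFactors = FALSE)
  }))
  ch$block_t_starts <- ch$block_q_starts <- ch$block_sizes <- NULL
  structure(list(chains = ch, blocks = blocks),
            class = "alignment_chains")
}
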