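#' Protein-guided codon alignment of two CDS sequences
#'
#' Mirrors the standard MUSCLE + pal2nal route for a pair: the two proteins
#' are globally aligned (BLOSUM62, affine gaps 11/1) and each protein gap is
#' expanded to a codon triplet gap in the CDS.  Columns where either
#' sequence has a gap or a stop codon are excluded from `n_codons` and from
#' all downstream likelihood computation (complete deletion).
#'
#' @param cds_a,cds_b character or [Biostrings::DNAString] coding sequences
#'   (terminal stop codons allowed and removed).  Each protein must
#'   translate its CDS exactly.
#' @param ids optional character(2) of sequence identifiers.
#' @return object of class `codon_alignment`: list with `a`, `b` (aligned
#'   codon vectors including `"---"` gaps), `used` (logical, columns used:
#'   gap-free and stop-free), `n_codons` (number of used columns) and
#'   `ids`.
#' @export
align_codons <- function(cds_a, cds_b, ids = c("a", "b")) {
  sa <- strip_stop(as.character(cds_a))
  sb <- strip_stop(as.character(cds_b))
  pa <- translate_cds(sa, ids[1])
  pb <- translate_cds(sb, ids[2])
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  codon_alignment_from_proteins(ap, as_, sa, sb, ids)
}

codon_alignment_from_proteins <- function(ap, as_, cds_a, cds_b, ids) {
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  a <- rep("---", length(ap)); b <- rep("---", length(as_))
  a[ap != "-"] <- ca
  b[as_ != "-"] <- cb
  tab <- codon_tables()
  used <- a %in% tab$codons & b %in% tab$codons
  structure(list(a = a, b = b, used = used, n_codons = sum(used),
                 ids = ids),
            class = "codon_alignment")
}

strip_stop <- function(s) {
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  last <- substr(s, nchar(s) - 2L, nchar(s))
  if (Biostrings::GENETIC_CODE[[last]] == "*") substr(s, 1L, nchar(s) - 3L)
  else s
}

translate_cds <- function(s, id) {
  p <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  if (grepl("\\*", substr(p, 1, nchar(p) - 1))) {
    stop("internal stop codon in CDS of ", id, " at codon ",
         regexpr("\\*", p))
  }
  sub("\\*$", "", p)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", x$ids[1], "vs", x$ids[2], "-", length(x$a),
      "columns,", x$n_codons, "used\n")
  invisible(x)
}

used_codons <- function(aln) list(a = aln$a[aln$used], b = aln$b[aln$used])

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Pathway-counting estimator used as an independent check on the
#' likelihood estimator: synonymous/nonsynonymous sites are counted per
#' codon (changes to stop codons count as nonsynonymous opportunity),
#' differences are averaged over all orderings of the changed positions,
#' excluding pathways that pass through a stop codon, and the proportions
#' are corrected with the Jukes-Cantor formula.
#'
#' @param aln a [codon_alignment].
#' @return list with `ka`, `ks` (NA with `saturated = TRUE` when the
#'   correction is undefined), the raw counts `N`, `S`, `Nd`, `Sd`, and
#'   `saturated`.
#' @export
ng86_kaks <- function(aln) {
  uc <- used_codons(aln)
  if (length(uc$a) == 0L) stop("no usable (gap- and stop-free) codon columns")
  gc <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")

  count_sites <- function(codon) {
    sp <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (alt in setdiff(nt, sp[pos])) {
        mut <- sp; mut[pos] <- alt
        mc <- paste(mut, collapse = "")
        if (gc[[mc]] != "*" && gc[[mc]] == gc[[codon]]) s <- s + 1 / 3
      }
    }
    c(S = s, N = 3 - s)
  }
  path_diffs <- function(c1, c2) {
    sp1 <- strsplit(c1, "")[[1]]; sp2 <- strsplit(c2, "")[[1]]
    d <- which(sp1 != sp2)
    if (length(d) == 0L) return(c(Sd = 0, Nd = 0))
    perms <- if (length(d) == 1L) list(d) else {
      if (length(d) == 2L) list(d, rev(d)) else {
        p <- list()
        for (i in 1:3) for (j in setdiff(1:3, i)) {
          p[[length(p) + 1L]] <- d[c(i, j, setdiff(1:3, c(i, j)))]
        }
        p
      }
    }
    acc <- c(Sd = 0, Nd = 0); nok <- 0L
    for (ord in perms) {
      cur <- sp1; sd <- 0; nd <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- sp2[pos]
        a1 <- gc[[paste(cur, collapse = "")]]
        a2 <- gc[[paste(nxt, collapse = "")]]
        if (a2 == "*") { ok <- FALSE; break }
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { acc <- acc + c(Sd = sd, Nd = nd); nok <- nok + 1L }
    }
    if (nok == 0L) {
      ## all pathways pass through a stop: fall back to counting every path
      return(c(Sd = 0, Nd = length(d)))
    }
    acc / nok
  }

  sites <- vapply(uc$a, count_sites, c(S = 0, N = 0)) +
    vapply(uc$b, count_sites, c(S = 0, N = 0))
  S <- sum(sites["S", ]) / 2
  N <- sum(sites["N", ]) / 2
  diffs <- vapply(seq_along(uc$a),
                  function(i) path_diffs(uc$a[i], uc$b[i]),
                  c(Sd = 0, Nd = 0))
  Sd <- sum(diffs["Sd", ]); Nd <- sum(diffs["Nd", ])
  jc <- function(p) {
    if (p >= 0.749999) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ks <- jc(Sd / S); ka <- jc(Nd / N)
  list(ka = ka, ks = ks, N = N, S = S, Nd = Nd, Sd = Sd,
       saturated = is.na(ka) || is.na(ks))
}

#' Likelihood-ratio test p-value (chi-square, df = 1)
#'
#' @param lnL_alt log-likelihood of the alternative (free-omega) model.
#' @param lnL_null log-likelihood of the null (fixed-omega) model.
#' @param tol numerical tolerance: a deficit `lnL_alt < lnL_null` within
#'   `tol` is clamped to zero; a larger deficit is an optimizer failure.
#' @return p-value.
#' @export
lrt <- function(lnL_alt, lnL_null, tol = 1e-3) {
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < -2 * tol) {
    stop("lnL_alt < lnL_null beyond tolerance (2*delta = ",
         format(stat), "): optimizer failure")
  }
  stat <- max(stat, 0)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Run the fixed-omega selection test for one sequence pair
#'
#' Fits the free-omega and fixed-omega GY94 models to a protein-guided
#' codon alignment and performs the likelihood-ratio test.  Pairs with
#' fewer than `min_codons` usable codon columns are flagged `too_short`
#' and not tested.
#'
#' @param cds_a,cds_b coding sequences (focal gene first).
#' @param null_omega the fixed omega of the null model: 0.5 for the paralog
#'   constraint test, 1.0 for the de novo neutrality test.
#' @param ids identifiers for the pair.
#' @param min_codons minimum usable codon columns (default 30).
#' @return one-row data.frame with columns `gene_id`, `partner_id`, `ka`,
#'   `ks`, `omega_hat`, `lnL_alt`, `lnL_null`, `p_value`, `null_omega`,
#'   `n_codons`, `filtered`, `verdict`.
#' @export
selection_test <- function(cds_a, cds_b, null_omega = 0.5,
                           ids = c("a", "b"), min_codons = 30L) {
  aln <- align_codons(cds_a, cds_b, ids)
  if (aln$n_codons < min_codons) {
    return(data.frame(gene_id = ids[1], partner_id = ids[2],
                      ka = NA_real_, ks = NA_real_, omega_hat = NA_real_,
                      lnL_alt = NA_real_, lnL_null = NA_real_,
                      p_value = NA_real_, null_omega = null_omega,
                      n_codons = aln$n_codons, filtered = "too_short",
                      verdict = "filtered", stringsAsFactors = FALSE))
  }
  counts <- codon_pair_counts(aln)
  alt <- fit_gy94_counts(counts, fix_omega = NULL)
  null <- fit_gy94_counts(counts, fix_omega = null_omega)
  p <- lrt(alt$lnL, null$lnL)
  data.frame(gene_id = ids[1], partner_id = ids[2],
             ka = alt$ka, ks = alt$ks, omega_hat = alt$omega_hat,
             lnL_alt = alt$lnL, lnL_null = null$lnL, p_value = p,
             null_omega = null_omega, n_codons = aln$n_codons,
             filtered = "none", verdict = NA_character_,
             stringsAsFactors = FALSE)
}

#' Apply the Ka/Ks exclusion filters and call verdicts
#'
#' Pairs are excluded when `Ka > 0.5` or `Ks > 5` (implausible paralog
#' divergence), then Ks outliers beyond 1.5 interquartile ranges of the
#' remaining Ks distribution (quartiles by linear interpolation,
#' [stats::quantile] type 7) are excluded.  Remaining pairs get a verdict:
#' `negative_selection` when `omega_hat < null_omega` and `p < alpha`, else
#' `not_significant`.
#'
#' @param results data.frame as returned by rbind-ing [selection_test]
#'   rows.
#' @param alpha significance threshold (default 0.05).
#' @return the data.frame with `filtered` and `verdict` updated.
#' @export
ks_filter <- function(results, alpha = 0.05) {
  r <- results
  pre <- r$filtered == "none"
  flag_ka <- pre & !is.na(r$ka) & r$ka > 0.5
  r$filtered[flag_ka] <- "ka_gt_0.5"
  flag_ks <- r$filtered == "none" & !is.na(r$ks) & r$ks > 5
  r$filtered[flag_ks] <- "ks_gt_5"
  pool <- which(r$filtered == "none" & !is.na(r$ks))
  if (length(pool) >= 4L) {
    q <- stats::quantile(r$ks[pool], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    out <- pool[r$ks[pool] < q[1] - 1.5 * iqr | r$ks[pool] > q[2] + 1.5 * iqr]
    r$filtered[out] <- "ks_iqr_outlier"
  } else if (length(pool) > 0L) {
    warning("fewer than 4 unfiltered Ks values; IQR filter skipped")
  }
  keep <- r$filtered == "none"
  r$verdict[!keep] <- "filtered"
  r$verdict[keep] <- ifelse(
    !is.na(r$p_value[keep]) & r$p_value[keep] < alpha &
      r$omega_hat[keep] < r$null_omega[keep],
    "negative_selection", "not_significant")
  r
}

#' Recover the orthologous ORF of a de novo gene from a sister genome
#'
#' The homologous region (from reciprocal-best chains) is extended by
#' `flank` bp on both sides (truncated at chromosome edges), translated in
#' all six frames, and maximal stop-free stretches of at least `min_codons`
#' codons are aligned to the de novo protein (local, BLOSUM62, gaps 11/1).
#' Among candidates whose alignment score passes `score_floor`, the longest
#' ORF is returned.
#'
#' @param protein the de novo gene's protein (character or AAString).
#' @param genome sister-species genome ([Biostrings::DNAStringSet]).
#' @param chrom,start,end homologous interval (1-based closed).
#' @param flank bp of flank to add each side (default 10000, mirroring the
#'   10 kb extension of the published procedure).
#' @param min_codons minimum ORF length in codons (default 30).
#' @param score_floor minimum protein alignment score (default 50).
#' @return `NULL` if no acceptable ORF, else list with `dna`, `protein`,
#'   `score`.
#' @export
de_novo_ortholog_orf <- function(protein, genome, chrom, start, end,
                                 flank = 10000L, min_codons = 30L,
                                 score_floor = 50) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- Biostrings::width(genome[chrom])
  if (start > L || end < 1L) stop("homolog location outside genome")
  a <- max(1L, start - flank); b <- min(L, end + flank)
  region <- Biostrings::subseq(genome[[chrom]], a, b)
  prot <- Biostrings::AAString(as.character(protein))

  cands <- list()
  for (s in list(region, Biostrings::reverseComplement(region))) {
    for (off in 0:2) {
      sub <- Biostrings::subseq(s, off + 1L,
                                off + ((Biostrings::nchar(s) - off) %/% 3) * 3)
      if (Biostrings::nchar(sub) < 3L * min_codons) next
      aa <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
      ## maximal stop-free stretches
      pieces <- gregexpr("[^*]+", aa)[[1]]
      for (i in seq_along(pieces)) {
        st <- pieces[i]; len <- attr(pieces, "match.length")[i]
        if (len < min_codons) next
        cands[[length(cands) + 1L]] <- list(
          dna = as.character(Biostrings::subseq(sub, (st - 1L) * 3L + 1L,
                                                (st - 1L + len) * 3L)),
          protein = substr(aa, st, st + len - 1L))
      }
    }
  }
  if (length(cands) == 0L) return(NULL)
  scores <- vapply(cands, function(cc) {
    Biostrings::pairwiseAlignment(
      prot, Biostrings::AAString(cc$protein),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
  }, 0)
  ok <- which(scores >= score_floor)
  if (length(ok) == 0L) return(NULL)
  best <- ok[which.max(nchar(vapply(cands[ok], `[[`, "", "protein")))]
  c(cands[[best]], list(score = scores[best]))
}
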