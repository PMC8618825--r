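#' Call expression evidence and tissue breadth from an FPKM matrix
#'
#' Replicates are collapsed by their mean per tissue before thresholding.
#' A gene is expressed when its per-tissue mean FPKM is strictly above
#' `threshold` in at least one tissue; breadth is the number of tissues
#' above the threshold.
#'
#' @param em an `expression_matrix` of type `"fpkm"`.
#' @param threshold FPKM threshold (strict `>`; default 0.5).
#' @return data.frame with `gene_id`, `expressed`, `breadth`, and one
#'   `fpkm.<tissue>` column per tissue (replicate means).
#' @export
call_expression <- function(em, threshold = 0.5) {
  stopifnot(inherits(em, "expression_matrix"), em$type == "fpkm")
  if (any(rowSums(!is.na(em$values)) == 0)) {
    stop("gene(s) with all-missing expression values")
  }
  tissues <- unique(em$meta$tissue)
  tmeans <- vapply(tissues, function(tt) {
    rowMeans(em$values[, em$meta$tissue == tt, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (is.null(dim(tmeans))) tmeans <- matrix(tmeans, nrow = 1)
  above <- tmeans > threshold
  out <- data.frame(gene_id = rownames(em$values),
                    expressed = rowSums(above) > 0,
                    breadth = as.integer(rowSums(above)),
                    stringsAsFactors = FALSE)
  colnames(tmeans) <- paste0("fpkm.", tissues)
  cbind(out, as.data.frame(tmeans, row.names = NULL))
}

#' Compare expression between gene age groups
#'
#' Genes are split into an old group (branches `0..old_max`) and a young
#' group (branches `old_max+1..B`).  For each gene the median FPKM across
#' tissues (of replicate means) is computed; groups are compared on the
#' log2 scale (pseudocount 1) with a two-sided Wilcoxon rank-sum test, and
#' breadth distributions are summarised.
#'
#' @param ages data.frame with `gene_id` and `branch` (from the age-dating
#'   stage).
#' @param em FPKM `expression_matrix`.
#' @param old_max highest branch index counted as old (default 1).
#' @param threshold FPKM threshold for breadth (default 0.5).
#' @return list with `summary` (per-group n, median FPKM, median log2
#'   expression, median breadth), `p_value` (rank-sum), and the per-gene
#'   table `genes`.
#' @export
age_group_stats <- function(ages, em, old_max = 1L, threshold = 0.5) {
  calls <- call_expression(em, threshold)
  tiss_cols <- grep("^fpkm\\.", names(calls))
  med <- apply(calls[, tiss_cols, drop = FALSE], 1L, stats::median)
  d <- merge(ages[, c("gene_id", "branch")],
             data.frame(gene_id = calls$gene_id, median_fpkm = med,
                        breadth = calls$breadth), by = "gene_id")
  d$group <- ifelse(d$branch <= old_max, "old", "young")
  if (!all(c("old", "young") %in% d$group)) {
    stop("both age groups must be non-empty")
  }
  d$log2_fpkm <- log2(d$median_fpkm + 1)
  w <- stats::wilcox.test(log2_fpkm ~ group, data = d, exact = FALSE)
  summ <- do.call(rbind, lapply(split(d, d$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               median_fpkm = stats::median(g$median_fpkm),
               median_log2 = stats::median(g$log2_fpkm),
               median_breadth = stats::median(g$breadth))
  }))
  rownames(summ) <- NULL
  list(summary = summ, p_value = w$p.value, genes = d)
}

#' Tissue expression breakdown for de novo genes
#'
#' @param calls output of [call_expression] restricted to de novo genes.
#' @return list with `per_tissue` (named counts of genes expressed in each
#'   tissue), `n_expressed`, `all_tissues`, `single_tissue`,
#'   `multi_tissue` counts.
#' @export
de_novo_tissue_counts <- function(calls) {
  tiss_cols <- grep("^fpkm\\.", names(calls), value = TRUE)
  above <- as.matrix(calls[, tiss_cols, drop = FALSE]) > 0.5
  colnames(above) <- sub("^fpkm\\.", "", tiss_cols)
  n_tiss <- rowSums(above)
  list(per_tissue = colSums(above),
       n_expressed = sum(n_tiss > 0),
       all_tissues = sum(n_tiss == length(tiss_cols)),
       single_tissue = sum(n_tiss == 1),
       multi_tissue = sum(n_tiss > 1 & n_tiss < length(tiss_cols)))
}

#' Median-of-ratios size factors
#'
#' @param counts integer matrix (genes x samples).
#' @return numeric vector of per-sample size factors (geometric-mean
#'   reference, median ratio over genes with all-positive counts).
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg)                       # log geometric mean
  use <- is.finite(ref)
  if (!any(use)) return(rep(1, ncol(counts)))
  sf <- apply(lg[use, , drop = FALSE], 2L, function(x) {
    exp(stats::median(x - ref[use], na.rm = TRUE))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  unname(sf)
}

#' Negative-binomial Wald test for left/right differential expression
#'
#' A fully specified, deterministic two-group test on raw counts:
#' size factors by median-of-ratios across all samples, per-gene dispersion
#' by method-of-moments on normalized counts pooled over both sides
#' (floored at `1e-8`), then a Wald test of the log2 fold change
#' (right vs left) with the NB variance `mu + alpha * mu^2` propagated to
#' the log scale.  The Wald statistic is referred to a t distribution with
#' `nL + nR - 2` degrees of freedom (small-sample reference for triplicate
#' designs).  All-zero genes get `lfc = 0`, `p = 1`.
#'
#' @param counts integer matrix (genes x samples) for one stage/tissue.
#' @param side character vector (`"L"`/`"R"`) per column.
#' @param alpha significance threshold for the `significant` flag
#'   (raw p, default 0.05).
#' @param pseudo pseudocount added to normalized means for the fold change
#'   (default 0.5).
#' @return data.frame with `gene_id`, `lfc` (log2 right/left), `se`,
#'   `stat`, `p_value`, `padj` (BH, reported for transparency only) and
#'   `significant` (raw `p < alpha`).
#' @export
nb_differential_test <- function(counts, side, alpha = 0.05, pseudo = 0.5) {
  stopifnot(ncol(counts) == length(side), all(side %in% c("L", "R")),
            sum(side == "L") >= 2L, sum(side == "R") >= 2L)
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("counts must be non-negative integers")
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  iL <- side == "L"; iR <- side == "R"
  nL <- sum(iL); nR <- sum(iR)

  mL <- rowMeans(norm[, iL, drop = FALSE])
  mR <- rowMeans(norm[, iR, drop = FALSE])
  ## method-of-moments dispersion on normalized counts, within-group
  ## (pooled residual variance around each side mean)
  vWithin <- (rowSums((norm[, iL, drop = FALSE] - mL)^2) +
                rowSums((norm[, iR, drop = FALSE] - mR)^2)) / (nL + nR - 2)
  mPool <- (mL * nL + mR * nR) / (nL + nR)
  disp <- (vWithin - mPool) / pmax(mPool, 1e-8)^2
  disp <- pmax(disp, 1e-8)

  lfc <- log2((mR + pseudo) / (mL + pseudo))
  varL <- (mL + disp * mL^2) / nL
  varR <- (mR + disp * mR^2) / nR
  se <- sqrt(varL / pmax(mL + pseudo, 1e-8)^2 +
               varR / pmax(mR + pseudo, 1e-8)^2) / log(2)
  se <- pmax(se, 1e-8)
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df = nL + nR - 2)
  zero <- mL == 0 & mR == 0
  lfc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1
  data.frame(gene_id = rownames(counts), lfc = lfc, se = se, stat = stat,
             p_value = p, padj = stats::p.adjust(p, "BH"),
             significant = p < alpha, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Left/right asymmetric expression across stages and tissues
#'
#' Runs [nb_differential_test] separately for every stage/tissue
#' combination of a count `expression_matrix`.
#'
#' @param em `expression_matrix` of type `"counts"` with `side`, `stage`,
#'   `tissue` metadata.
#' @param genes optional character vector restricting the tested genes.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame of per-gene results with `stage` and `tissue`
#'   columns prepended.
#' @export
asymmetry_tests <- function(em, genes = NULL, alpha = 0.05) {
  stopifnot(inherits(em, "expression_matrix"), em$type == "counts")
  v <- em$values
  if (!is.null(genes)) v <- v[rownames(v) %in% genes, , drop = FALSE]
  combos <- unique(em$meta[, c("stage", "tissue")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- em$meta$stage == combos$stage[i] & em$meta$tissue == combos$tissue[i]
    r <- nb_differential_test(v[, sel, drop = FALSE], em$meta$side[sel],
                              alpha = alpha)
    cbind(stage = combos$stage[i], tissue = combos$tissue[i], r)
  })
  do.call(rbind, out)
}
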