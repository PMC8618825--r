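#' Read a genome FASTA file
#'
#' Sequences are uppercased; only `A`, `C`, `G`, `T`, `N` are expected.
#' Duplicate headers are rejected.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet], one entry per chromosome or
#'   scaffold.  Names are the first whitespace-delimited token of each
#'   header.
#' @export
read_genome <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA in ", path, ": line 1 does not start with '>'")
  }
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicated FASTA header(s) in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  chr <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(x)[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Write a genome FASTA file
#' @param genome named [Biostrings::DNAStringSet] (or named character).
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Construct a gene-model set
#'
#' The package-wide container for gene annotations: a `genes` table and a
#' `features` table of exon and CDS intervals (1-based, closed, as
#' throughout the package; all interval arithmetic is delegated to
#' IRanges).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `placed` (logical: on a chromosome vs an unplaced
#'   scaffold), `cds_ok` (logical: CDS length divisible by 3, usable for
#'   selection analysis).
#' @param features data.frame with columns `gene_id`, `transcript_id`,
#'   `type` (`exon` or `CDS`), `chrom`, `start`, `end`, `strand`.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, features) {
  stopifnot(all(c("gene_id", "chrom", "strand", "placed", "cds_ok")
                %in% names(genes)),
            all(c("gene_id", "transcript_id", "type", "chrom", "start",
                  "end", "strand") %in% names(features)))
  features <- features[order(features$gene_id, features$transcript_id,
                             features$type, features$start), , drop = FALSE]
  rownames(genes) <- rownames(features) <- NULL
  obj <- structure(list(genes = genes, features = features),
                   class = "gene_models")
  validate_gene_models(obj)
  obj
}

validate_gene_models <- function(gm) {
  f <- gm$features
  for (tid in unique(f$transcript_id)) {
    ex <- f[f$transcript_id == tid & f$type == "exon", ]
    if (nrow(ex) > 1L) {
      o <- order(ex$start)
      if (any(ex$end[o][-nrow(ex)] >= ex$start[o][-1L])) {
        stop("overlapping exons within transcript ", tid)
      }
    }
    cds <- f[f$transcript_id == tid & f$type == "CDS", ]
    if (nrow(cds) && nrow(ex)) {
      cov <- IRanges::findOverlaps(
        IRanges::IRanges(cds$start, cds$end),
        IRanges::IRanges(ex$start, ex$end), type = "within")
      if (length(cov) < nrow(cds)) {
        stop("CDS not contained in exons for transcript ", tid)
      }
    }
  }
  invisible(gm)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      length(unique(x$features$transcript_id)), "transcripts\n")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Expects `gene`, `mRNA`, `exon` and `CDS` features linked by `ID`/`Parent`
#' attributes.  Genes whose CDS length (per transcript, after removing a
#' terminal stop codon) is not divisible by 3 are flagged `cds_ok = FALSE`
#' with a warning and kept; they are unusable for selection analysis only.
#'
#' @param path GFF3 file.
#' @param chromosomes optional character vector of placed chromosome names;
#'   genes on other sequences are flagged `placed = FALSE`.
#' @return a [gene_models] object.
#' @export
read_gene_models <- function(path, chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  id <- as.character(df$ID)
  par <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  gidx <- df$type == "gene"
  midx <- df$type == "mRNA"
  tid2gid <- stats::setNames(par[midx], id[midx])
  genes <- data.frame(gene_id = id[gidx], chrom = df$seqnames[gidx],
                      strand = df$strand[gidx], stringsAsFactors = FALSE)
  fidx <- df$type %in% c("exon", "CDS")
  features <- data.frame(
    gene_id = unname(tid2gid[par[fidx]]),
    transcript_id = par[fidx],
    type = as.character(df$type[fidx]),
    chrom = df$seqnames[fidx],
    start = df$start[fidx], end = df$end[fidx],
    strand = df$strand[fidx], stringsAsFactors = FALSE)
  if (anyNA(features$gene_id)) stop("GFF3 exon/CDS with unknown mRNA parent")

  genes$placed <- if (is.null(chromosomes)) TRUE else genes$chrom %in% chromosomes
  cds_len <- tapply(
    (features$end - features$start + 1L)[features$type == "CDS"],
    features$transcript_id[features$type == "CDS"], sum)
  ## a terminal stop may or may not be annotated inside the CDS; accept both
  ok_tid <- names(cds_len)[cds_len %% 3L == 0L]
  gene_ok <- tapply(features$transcript_id %in% ok_tid, features$gene_id, all)
  genes$cds_ok <- unname(gene_ok[genes$gene_id])
  genes$cds_ok[is.na(genes$cds_ok)] <- FALSE
  if (any(!genes$cds_ok)) {
    warning(sum(!genes$cds_ok), " gene(s) with CDS length not divisible by 3; ",
            "flagged unusable for selection analysis")
  }
  gene_models(genes, features)
}

#' Write gene models to a GFF3 file
#' @param gm a [gene_models] object.
#' @param path output file.
#' @export
write_gene_models <- function(gm, path) {
  f <- gm$features
  g <- gm$genes
  gene_rng <- do.call(rbind, lapply(split(f, f$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end), strand = d$strand[1])
  }))
  tx <- unique(f[, c("gene_id", "transcript_id", "chrom", "strand")])
  tx_rng <- do.call(rbind, lapply(split(f, f$transcript_id), function(d) {
    data.frame(transcript_id = d$transcript_id[1], start = min(d$start),
               end = max(d$end))
  }))
  tx <- merge(tx, tx_rng, by = "transcript_id")

  gr_gene <- GenomicRanges::GRanges(
    gene_rng$chrom, IRanges::IRanges(gene_rng$start, gene_rng$end),
    strand = gene_rng$strand, type = "gene", ID = gene_rng$gene_id,
    Parent = NA_character_, phase = NA_integer_)
  gr_mrna <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
    type = "mRNA", ID = tx$transcript_id,
    Parent = as.character(tx$gene_id), phase = NA_integer_)
  ## GFF3 phase for CDS rows: codon offset given the CDS bases already
  ## emitted 5' of each piece
  f$phase <- NA_integer_
  for (tid in unique(f$transcript_id[f$type == "CDS"])) {
    i <- which(f$transcript_id == tid & f$type == "CDS")
    i <- if (f$strand[i[1]] == "-") i[order(-f$start[i])] else
      i[order(f$start[i])]
    before <- cumsum(c(0L, (f$end[i] - f$start[i] + 1L)[-length(i)]))
    f$phase[i] <- (3L - before %% 3L) %% 3L
  }
  gr_feat <- GenomicRanges::GRanges(
    f$chrom, IRanges::IRanges(f$start, f$end), strand = f$strand,
    type = f$type, ID = NA_character_,
    Parent = as.character(f$transcript_id), phase = f$phase)
  gr <- suppressWarnings(c(gr_gene, gr_mrna, gr_feat))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a repeat track from a BED file
#'
#' @param path BED file (0-based half-open on disk; converted on import).
#' @return a [GenomicRanges::GRanges] of merged (non-overlapping) repeat
#'   intervals.
#' @export
read_repeats <- function(path) {
  GenomicRanges::reduce(rtracklayer::import(path, format = "bed"))
}

#' Write a repeat track to a BED file
#' @param repeats a [GenomicRanges::GRanges].
#' @param path output file.
#' @export
write_repeats <- function(repeats, path) {
  rtracklayer::export(GenomicRanges::reduce(repeats), path, format = "bed")
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' The first column must be `gene_id`; remaining column names encode the
#' sample metadata as dot-separated fields: `tissue.replicate` for FPKM
#' matrices and `tissue.side.stage.replicate` (side in `L`/`R`) for count
#' matrices.
#'
#' @param path TSV file with a header row.
#' @param type `"fpkm"` (non-negative reals) or `"counts"` (non-negative
#'   integers).
#' @return an object of class `expression_matrix`: list with `values`
#'   (numeric matrix, genes x samples), `meta` (data.frame of per-column
#'   metadata) and `type`.
#' @export
read_expression_matrix <- function(path, type = c("fpkm", "counts")) {
  type <- match.arg(type)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(d)[1] == "gene_id")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  expression_matrix(m, type = type)
}

#' Construct an expression matrix with parsed column metadata
#' @param values numeric matrix (genes x samples) with encoded column names
#'   (see [read_expression_matrix]).
#' @param type `"fpkm"` or `"counts"`.
#' @export
expression_matrix <- function(values, type = c("fpkm", "counts")) {
  type <- match.arg(type)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (type == "counts" && any(values != round(values))) {
    stop("count matrix must be integer-valued")
  }
  parts <- strsplit(colnames(values), ".", fixed = TRUE)
  nf <- lengths(parts)
  meta <- if (type == "fpkm") {
    if (any(nf != 2L)) stop("FPKM column names must be 'tissue.replicate'")
    data.frame(sample = colnames(values),
               tissue = vapply(parts, `[`, "", 1L),
               replicate = vapply(parts, `[`, "", 2L))
  } else {
    if (any(nf != 4L)) {
      stop("count column names must be 'tissue.side.stage.replicate'")
    }
    data.frame(sample = colnames(values),
               tissue = vapply(parts, `[`, "", 1L),
               side = vapply(parts, `[`, "", 2L),
               stage = vapply(parts, `[`, "", 3L),
               replicate = vapply(parts, `[`, "", 4L))
  }
  if (type == "counts" && !all(meta$side %in% c("L", "R"))) {
    stop("count matrix 'side' field must be L or R")
  }
  structure(list(values = values, meta = meta, type = type),
            class = "expression_matrix")
}

#' Write an expression matrix to TSV
#' @param em an `expression_matrix`.
#' @param path output file.
#' @export
write_expression_matrix <- function(em, path) {
  d <- data.frame(gene_id = rownames(em$values), em$values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract per-transcript CDS sequences
#'
#' @param gm a [gene_models] object.
#' @param genome a named [Biostrings::DNAStringSet].
#' @return named [Biostrings::DNAStringSet] of spliced CDS, one per
#'   transcript, minus-strand transcripts reverse-complemented.
#' @export
cds_sequences <- function(gm, genome) {
  f <- gm$features[gm$features$type == "CDS", ]
  out <- vapply(split(f, f$transcript_id), function(d) {
    d <- d[order(d$start), ]
    s <- paste(vapply(seq_len(nrow(d)), function(i)
      as.character(Biostrings::subseq(genome[[d$chrom[i]]],
                                      d$start[i], d$end[i])), ""),
      collapse = "")
    if (d$strand[1] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, "")
  Biostrings::DNAStringSet(out)
}

#' Build the focal proteome from the longest transcript of each gene
#'
#' One protein per gene with a valid CDS: the longest transcript is
#' retained, its CDS translated with the standard code, and any terminal
#' stop removed.
#'
#' @inheritParams cds_sequences
#' @return named [Biostrings::AAStringSet], names are gene ids.
#' @export
proteome <- function(gm, genome) {
  cds <- cds_sequences(gm, genome)
  f <- gm$features[gm$features$type == "CDS", ]
  tx2gene <- stats::setNames(
    vapply(split(f$gene_id, f$transcript_id), `[`, "", 1L),
    names(split(f$gene_id, f$transcript_id)))
  ok_genes <- gm$genes$gene_id[gm$genes$cds_ok]
  keep <- names(cds)[tx2gene[names(cds)] %in% ok_genes]
  cds <- cds[keep]
  len <- Biostrings::width(cds)
  pick <- tapply(seq_along(cds), tx2gene[names(cds)],
                 function(i) i[which.max(len[i])])
  cds <- cds[unlist(pick)]
  names(cds) <- names(pick)
  aa <- Biostrings::translate(cds, if.fuzzy.codon = "solve")
  ## strip terminal stop
  Biostrings::AAStringSet(sub("\\*$", "", as.character(aa)))
}
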