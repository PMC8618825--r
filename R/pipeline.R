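#' Align every query genome to the focal genome and net reciprocal-best
#'
#' The parameter preset tightens or loosens with the split age of each
#' query (nearer species use stricter seeding).
#'
#' @param sim a `genome_simulation` (or any list with `genomes`, `repeats`
#'   and `ladder` fields of the same shape).
#' @param params optional single [align_params] list used for all species
#'   (overrides the per-divergence presets).
#' @return named list of netted `alignment_chains`, one per query species.
#' @export
align_ladder <- function(sim, params = NULL) {
  ladder <- sim$ladder
  focal <- sim$genomes[[ladder$focal]]
  split_age <- function(sp) {
    for (i in seq_len(nrow(ladder$splits))) {
      if (sp %in% ladder$splits$clade[[i]]) return(ladder$splits$age[i])
    }
    NA_real_
  }
  chains <- list()
  for (sp in setdiff(names(sim$genomes), ladder$focal)) {
    p <- params
    if (is.null(p)) {
      age <- split_age(sp)
      p <- if (age <= 55) align_params("near")
      else if (age <= 75) align_params("mid") else align_params("far")
    }
    f2q <- align_genomes(focal, sim$genomes[[sp]], p,
                         target_mask = sim$repeats)
    q2f <- align_genomes(sim$genomes[[sp]], focal, p)
    chains[[sp]] <- reciprocal_best_net(f2q, q2f)
  }
  chains
}

#' Date all focal genes and apply the exclusion filters
#'
#' @param sim a `genome_simulation`.
#' @param chains from [align_ladder].
#' @param threshold presence threshold on exon coverage (default 0.5).
#' @param repeat_max repeat-overlap exclusion threshold (default 0.70).
#' @return age-call data.frame (see [assign_branch], [apply_filters]).
#' @export
date_genes <- function(sim, chains, threshold = 0.5, repeat_max = 0.70) {
  gm <- sim$models[[sim$ladder$focal]]
  prof <- call_presence(gm, chains, threshold)
  ages <- assign_branch(prof, sim$ladder)
  apply_filters(ages, gm, sim$repeats, repeat_max)
}

#' Paralog and de novo selection tests for classified new genes
#'
#' Duplicates (DNA- and RNA-mediated) are tested against their closest
#' paralog with the fixed-omega 0.5 likelihood-ratio test, then passed
#' through the Ka/Ks exclusion filters.  De novo genes are tested against
#' the reconstructed orthologous ORF of the sister genome (when their
#' homologous region maps there) with the fixed-omega 1.0 neutrality
#' test.
#'
#' @param sim a `genome_simulation`.
#' @param mech mechanism calls from [classify_mechanisms].
#' @param chains netted chains from [align_ladder].
#' @param sister the sister species name; defaults to the shallowest
#'   split of the ladder.
#' @return list with `paralog` and `de_novo` result data.frames.
#' @export
selection_analysis <- function(sim, mech, chains, sister = NULL) {
  ladder <- sim$ladder
  gm <- sim$models[[ladder$focal]]
  genome <- sim$genomes[[ladder$focal]]
  cds <- cds_sequences(gm, genome)
  tx_of <- function(g) paste0(g, ".t1")
  get_cds <- function(g) {
    tid <- tx_of(g)
    if (!tid %in% names(cds)) {
      f <- gm$features[gm$features$type == "CDS" & gm$features$gene_id == g, ]
      tid <- f$transcript_id[1]
    }
    as.character(cds[[tid]])
  }

  dup <- mech[mech$mechanism %in% c("dna_duplication", "retroposition"), ,
              drop = FALSE]
  paralog <- lapply(seq_len(nrow(dup)), function(i) {
    selection_test(get_cds(dup$gene_id[i]), get_cds(dup$parent_gene_id[i]),
                   null_omega = 0.5,
                   ids = c(dup$gene_id[i], dup$parent_gene_id[i]))
  })
  paralog <- if (length(paralog)) ks_filter(do.call(rbind, paralog)) else
    NULL

  if (is.null(sister)) {
    sister <- ladder$splits$clade[[nrow(ladder$splits)]][1]
  }
  dn <- mech[mech$mechanism == "de_novo", , drop = FALSE]
  prots <- proteome(gm, genome)
  ex <- gm$features[gm$features$type == "exon", , drop = FALSE]
  de_novo <- lapply(dn$gene_id, function(g) {
    if (!g %in% names(prots)) return(NULL)
    e <- ex[ex$gene_id == g, , drop = FALSE]
    gr <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end))
    qloc <- map_to_query(gr, chains[[sister]])
    if (length(qloc) == 0L) return(NULL)  # no homolog in the sister genome
    qc <- names(sort(table(as.character(GenomicRanges::seqnames(qloc))),
                     decreasing = TRUE))[1]
    qloc <- qloc[as.character(GenomicRanges::seqnames(qloc)) == qc]
    orf <- de_novo_ortholog_orf(prots[[g]], sim$genomes[[sister]], qc,
                                min(GenomicRanges::start(qloc)),
                                max(GenomicRanges::end(qloc)))
    if (is.null(orf)) return(NULL)
    r <- selection_test(get_cds(g), orf$dna, null_omega = 1,
                        ids = c(g, paste0(sister, "_orf")))
    r$verdict <- if (r$filtered != "none") "filtered"
    else if (!is.na(r$p_value) && r$p_value < 0.05 && r$omega_hat < 1)
      "negative_selection" else "not_significant"
    r
  })
  de_novo <- de_novo[!vapply(de_novo, is.null, TRUE)]
  de_novo <- if (length(de_novo)) do.call(rbind, de_novo) else NULL
  list(paralog = paralog, de_novo = de_novo)
}

#' Expression analysis of dated and classified genes
#'
#' @param sim a `genome_simulation`.
#' @param ages age calls.
#' @param mech mechanism calls.
#' @param lineage_min first lineage-specific branch (default 2).
#' @return list with `calls` (expression evidence), `age_groups`
#'   (old/young contrast), `de_novo_tissues`, `deg` (left/right tests for
#'   new genes present in the sister species, branches
#'   `lineage_min..B-1`), `deg_summary` (significant DEGs per
#'   stage/tissue).
#' @export
expression_analysis <- function(sim, ages, mech, lineage_min = 2L) {
  calls <- call_expression(sim$fpkm)
  ag <- age_group_stats(ages[!ages$excluded, ], sim$fpkm)
  dn <- calls[calls$gene_id %in% mech$gene_id[mech$mechanism == "de_novo"], ,
              drop = FALSE]
  dnt <- de_novo_tissue_counts(dn)
  B <- sim$ladder$n_branches
  testable <- ages$gene_id[!ages$excluded & ages$branch >= lineage_min &
                             ages$branch < B]
  deg <- asymmetry_tests(sim$counts, genes = testable)
  deg_summary <- stats::aggregate(significant ~ stage + tissue, deg, sum)
  names(deg_summary)[3] <- "n_significant"
  list(calls = calls, age_groups = ag, de_novo_tissues = dnt, deg = deg,
       deg_summary = deg_summary)
}

#' Assemble the pipeline report
#'
#' Every percentage in the report is recomputable from the printed
#' numerator and denominator; mechanism counts sum to the classified
#' lineage-specific total.
#'
#' @param ages,mech age and mechanism calls.
#' @param sel from [selection_analysis].
#' @param expr from [expression_analysis].
#' @param ladder a [species_ladder].
#' @param lineage_min first lineage-specific branch (default 2).
#' @return list of class `pipeline_report`.
#' @export
build_report <- function(ages, mech, sel, expr, ladder, lineage_min = 2L) {
  bs <- branch_summary(ages, ladder, lineage_min)
  ms <- partition_summary(mech)
  classified <- mech[mech$mechanism != "unclassified", , drop = FALSE]
  if (nrow(classified) &&
      !all(classified$gene_id %in% ages$gene_id)) {
    stop("gene-id mismatch between mechanism and age tables: ",
         paste(setdiff(classified$gene_id, ages$gene_id), collapse = ", "))
  }

  sel_summary <- list(tested = 0L, negative = 0L, pct_negative = NA)
  if (!is.null(sel$paralog)) {
    tested <- sum(sel$paralog$filtered == "none")
    neg <- sum(sel$paralog$verdict == "negative_selection")
    sel_summary <- list(tested = tested, negative = neg,
                        pct_negative = if (tested > 0)
                          proportion(neg, tested) else NA)
  }
  dn_sel <- list(tested = 0L, negative = 0L)
  if (!is.null(sel$de_novo)) {
    dn_sel <- list(tested = nrow(sel$de_novo),
                   negative = sum(sel$de_novo$verdict == "negative_selection"))
  }

  dup_ids <- classified$gene_id[classified$mechanism != "de_novo"]
  dn_ids <- classified$gene_id[classified$mechanism == "de_novo"]
  ec <- expr$calls
  dup_expr <- sum(ec$expressed[ec$gene_id %in% dup_ids])
  dn_expr <- sum(ec$expressed[ec$gene_id %in% dn_ids])

  rep <- list(
    per_branch = bs$per_branch,
    n_dated = bs$n_total,
    n_lineage_specific = bs$n_lineage_specific,
    pct_lineage_specific = bs$pct_lineage_specific,
    terminal_rate = bs$terminal_rate,
    lineage_rate = bs$lineage_rate,
    mechanisms = ms,
    n_classified = sum(ms$n[ms$mechanism != "unclassified"]),
    selection = sel_summary,
    de_novo_selection = dn_sel,
    expression = list(
      n_duplicates = length(dup_ids), duplicates_expressed = dup_expr,
      pct_duplicates_expressed = if (length(dup_ids))
        proportion(dup_expr, length(dup_ids)) else NA,
      n_de_novo = length(dn_ids), de_novo_expressed = dn_expr,
      pct_de_novo_expressed = if (length(dn_ids))
        proportion(dn_expr, length(dn_ids)) else NA,
      de_novo_tissues = expr$de_novo_tissues,
      age_group_p = expr$age_groups$p_value),
    deg_summary = expr$deg_summary)

  ## conservation identities
  stopifnot(sum(bs$per_branch$n) == bs$n_total)
  stopifnot(sum(ms$n[ms$mechanism != "unclassified"]) +
              ms$n[ms$mechanism == "unclassified"] == nrow(mech))
  class(rep) <- "pipeline_report"
  rep
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Gene ages (non-excluded genes):\n")
  print(x$per_branch, row.names = FALSE)
  cat(sprintf("lineage-specific: %d of %d dated genes (%.1f%%)\n",
              x$n_lineage_specific, x$n_dated, x$pct_lineage_specific))
  cat(sprintf("emergence rates: terminal %.1f /Myr, lineage %.1f /Myr\n",
              x$terminal_rate, x$lineage_rate))
  cat("Mechanisms:\n"); print(x$mechanisms, row.names = FALSE)
  cat(sprintf("Selection (paralog, omega0 = 0.5): %d tested, %d negative\n",
              x$selection$tested, x$selection$negative))
  cat(sprintf("Selection (de novo, omega0 = 1): %d tested, %d negative\n",
              x$de_novo_selection$tested, x$de_novo_selection$negative))
  cat(sprintf("Expression: %d/%d duplicates, %d/%d de novo expressed\n",
              x$expression$duplicates_expressed, x$expression$n_duplicates,
              x$expression$de_novo_expressed, x$expression$n_de_novo))
  cat("Significant left/right DEGs per stage/tissue:\n")
  print(x$deg_summary, row.names = FALSE)
  invisible(x)
}

#' Run the full analysis pipeline on a simulated ladder
#'
#' Simulation, alignment and netting, age dating, mechanism
#' classification, selection tests, expression analysis and report
#' assembly; deterministic for a given config.
#'
#' @param config a [simulation_config].
#' @param out_dir optional directory: stage outputs are written as TSV
#'   and the report as JSON.
#' @return list with all stage outputs (`sim`, `chains`, `ages`, `mech`,
#'   `sel`, `expr`, `report`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  sim <- simulate_genomes(config)
  chains <- align_ladder(sim)
  ages <- date_genes(sim, chains)
  qmods <- sim$models[setdiff(names(sim$models), sim$ladder$focal)]
  mech <- classify_mechanisms(ages, sim$models[[sim$ladder$focal]],
                              sim$genomes[[sim$ladder$focal]], chains,
                              qmods, sim$ladder)
  sel <- selection_analysis(sim, mech, chains)
  expr <- expression_analysis(sim, ages, mech)
  report <- build_report(ages, mech, sel, expr, sim$ladder)
  res <- list(sim = sim, chains = chains, ages = ages, mech = mech,
              sel = sel, expr = expr, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(ages, "ages.tsv")
    wt(mech, "mechanisms.tsv")
    if (!is.null(sel$paralog)) wt(sel$paralog, "selection_paralog.tsv")
    if (!is.null(sel$de_novo)) wt(sel$de_novo, "selection_de_novo.tsv")
    wt(expr$calls, "expression.tsv")
    wt(expr$deg, "deg.tsv")
    wt(sim$truth, "truth.tsv")
    jsonlite::write_json(
      report_to_json(report), file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

report_to_json <- function(rep) {
  r <- unclass(rep)
  r$per_branch <- as.list(r$per_branch)
  r$mechanisms <- as.list(r$mechanisms)
  r$deg_summary <- as.list(r$deg_summary)
  r
}

#' Read a simulation/pipeline configuration from a YAML file
#'
#' The file holds any subset of [simulation_config] arguments as
#' key-value pairs; `events` may be given as a list of
#' `{branch, mechanism, count}` records.  Unset keys keep the package
#' defaults.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a [simulation_config].
#' @export
read_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$events)) {
    y$events <- do.call(rbind, lapply(y$events, as.data.frame))
    y$events$branch <- as.integer(y$events$branch)
    y$events$count <- as.integer(y$events$count)
  }
  if (!is.null(seed)) y$seed <- seed
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(simulation_config, y)
}
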