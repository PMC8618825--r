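# Selection tests: paralog Ka/Ks with the fixed-omega 0.5 LRT and the
# Ka > 0.5 / Ks > 5 / 1.5-IQR exclusion filters for duplicates; the
# fixed-omega 1.0 neutrality LRT against the reconstructed sister ORF for
# de novo genes.

source("analysis/00_common.R")
sim <- readRDS(state_file("sim"))
chains <- readRDS(state_file("chains"))
mech <- readRDS(state_file("mech"))

sel <- selection_analysis(sim, mech, chains)
if (!is.null(sel$paralog)) {
  write.table(sel$paralog, file.path(res_dir, "selection_paralog.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tested <- sum(sel$paralog$filtered == "none")
  neg <- sum(sel$paralog$verdict == "negative_selection")
  cat(sprintf("paralog test: %d pairs, %d testable after filters, %d under negative selection\n",
              nrow(sel$paralog), tested, neg))
}
if (!is.null(sel$de_novo)) {
  write.table(sel$de_novo, file.path(res_dir, "selection_de_novo.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("de novo test: %d genes with sister ORFs, %d under negative selection\n",
              nrow(sel$de_novo),
              sum(sel$de_novo$verdict == "negative_selection")))
}
saveRDS(sel, state_file("sel"))
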