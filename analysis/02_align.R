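# Whole-genome homology: align every query genome to the focal genome in
# both directions (seed-and-extend, colinear chaining) and keep the
# reciprocal-best net.  Chains are written as PSL-like block tables.

source("analysis/00_common.R")
sim <- readRDS(state_file("sim"))

chains <- align_ladder(sim)
dir.create(file.path(res_dir, "chains"), showWarnings = FALSE)
for (sp in names(chains)) {
  write_chains(chains[[sp]], file.path(res_dir, "chains",
                                       paste0(sp, ".chains.tsv")))
  rb <- chains[[sp]]$chains
  cat(sprintf("%-8s %4d chains, %3d reciprocal-best, %8d bp netted\n",
              sp, nrow(rb), sum(rb$reciprocal_best),
              sum((rb$t_end - rb$t_start + 1)[rb$reciprocal_best])))
}
saveRDS(chains, state_file("chains"))
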