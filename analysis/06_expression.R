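# Expression evidence (FPKM > 0.5 in at least one tissue), tissue breadth,
# the old/young age-group contrast, and the left/right negative-binomial
# Wald tests per stage and tissue.

source("analysis/00_common.R")
sim <- readRDS(state_file("sim"))
ages <- readRDS(state_file("ages"))
mech <- readRDS(state_file("mech"))

expr <- expression_analysis(sim, ages, mech)
write.table(expr$calls, file.path(res_dir, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(expr$deg, file.path(res_dir, "deg.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("expressed genes: %d of %d\n", sum(expr$calls$expressed),
            nrow(expr$calls)))
cat(sprintf("old vs young expression: rank-sum p = %.3g\n",
            expr$age_groups$p_value))
cat("significant left/right DEGs per stage/tissue:\n")
print(expr$deg_summary, row.names = FALSE)
saveRDS(expr, state_file("expr"))
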