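# Origin-mechanism classification of the lineage-specific genes:
# closest-paralog search in the focal proteome, the multi-exon-parent /
# single-exon-child retrogene rule, and outgroup noncoding homology for
# de novo calls.

source("analysis/00_common.R")
sim <- readRDS(state_file("sim"))
chains <- readRDS(state_file("chains"))
ages <- readRDS(state_file("ages"))

qmods <- sim$models[setdiff(names(sim$models), sim$ladder$focal)]
mech <- classify_mechanisms(ages, sim$models[[sim$ladder$focal]],
                            sim$genomes[[sim$ladder$focal]], chains,
                            qmods, sim$ladder)
write.table(mech, file.path(res_dir, "mechanisms.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(partition_summary(mech), row.names = FALSE)

mm <- merge(mech, sim$truth, by = "gene_id")
cat(sprintf("planted-event mechanism recovery: %.1f%%\n",
            100 * mean(mm$mechanism == mm$true_mechanism)))
saveRDS(mech, state_file("mech"))
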