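# Simulate the study system: an 8-taxon dated ladder of ~2 Mb genomes with
# ~40 gene-birth events (DNA duplications, retropositions, de novo births)
# planted on the lineage-specific branches, plus expression matrices.
# Writes FASTA/GFF3/BED/TSV inputs for the downstream stages and the
# ground-truth event table.

source("analysis/00_common.R")

sim <- simulate_genomes(config)
write_simulation(sim, sim_dir)
saveRDS(sim, state_file("sim"))

cat(sprintf("simulated %d genomes; focal genome: %d genes on %d chromosomes\n",
            length(sim$genomes),
            nrow(sim$models[[sim$ladder$focal]]$genes),
            length(sim$chromosomes)))
cat(sprintf("planted events: %d (see %s/truth.tsv)\n", nrow(sim$truth),
            sim_dir))
print(table(branch = sim$truth$true_branch,
            mechanism = sim$truth$true_mechanism))
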