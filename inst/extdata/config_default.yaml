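# Reference study conditions: 8-taxon dated ladder, ~2 Mb focal genome,
# ~40 planted gene-birth events on the lineage-specific branches.
seed: 1
n_chromosomes: 2
chromosome_length: 1.0e+6
n_ancestral_genes: 150
substitution_rate: 5.0e-4
indel_rate: 2.0e-6
repeat_density: 0.05
frac_young_silent: 0.3
nb_dispersion: 0.05
asym_fold: 4
n_asym_genes: 10
events:
  - {branch: 2, mechanism: dna_duplication, count: 4}
  - {branch: 3, mechanism: dna_duplication, count: 4}
  - {branch: 4, mechanism: dna_duplication, count: 5}
  - {branch: 5, mechanism: dna_duplication, count: 6}
  - {branch: 2, mechanism: retroposition, count: 2}
  - {branch: 3, mechanism: retroposition, count: 2}
  - {branch: 4, mechanism: retroposition, count: 2}
  - {branch: 5, mechanism: retroposition, count: 2}
  - {branch: 2, mechanism: de_novo, count: 2}
  - {branch: 3, mechanism: de_novo, count: 2}
  - {branch: 4, mechanism: de_novo, count: 3}
  - {branch: 5, mechanism: de_novo, count: 3}
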