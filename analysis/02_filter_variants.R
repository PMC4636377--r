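#!/usr/bin/env Rscript
# Stage 2: apply the final-processing filters to the simulated population
# variant table and classify the mutation spectrum.
#
# Filters, in order: sub-telomeric removal (15-kb margins), static
# trajectories (absolute range <= 10%), then the haplotyping filters
# (multi-allelic sites, mixed zygosity across clones, peak frequency
# < 0.2) and the heterozygous 50% -> 100% cell-frequency adjustment.

suppressPackageStartupMessages(library(evoreseq))

sim <- "results/sim"
out_dir <- "results/variants"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

traj <- read_trajectories(file.path(sim, "trajectories.tsv"))
ann <- read_annotation(file.path(sim, "genes.tsv"),
                       file.path(sim, "chrom_lengths.tsv"))
clones <- utils::read.delim(file.path(sim, "clones.tsv"))
geno <- utils::read.delim(file.path(sim, "clone_genotypes.tsv"))

f1 <- filter_subtelomeric(traj, ann)
f2 <- filter_static_trajectories(f1)
f3 <- filter_for_haplotyping(f2, geno)
f4 <- adjust_heterozygous_frequencies(f3, geno, clones)

message(sprintf(
  "variants: %d observed -> %d after sub-telomeric -> %d after static -> %d for haplotyping (%d heterozygous adjustments)",
  nrow(traj), nrow(f1), nrow(f2), nrow(f3), nrow(attr(f4, "adjusted"))))

spectrum <- classify_mutations(traj, ann)
print(spectrum)

write_trajectories(f4, file.path(out_dir, "filtered_trajectories.tsv"))
utils::write.table(
  data.frame(metric = c("n_sites", "n_snp", "n_indel", "snp_coding",
                        "snp_noncoding", "indel_coding", "indel_noncoding",
                        "syn", "nonsyn"),
             value = c(spectrum$n_sites, spectrum$by_class,
                       spectrum$context$SNP, spectrum$context$indel,
                       spectrum$effect)),
  file.path(out_dir, "spectrum.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote filtered table and spectrum under ", out_dir)
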