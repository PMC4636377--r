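#!/usr/bin/env Rscript
# Stage 3: cluster the filtered trajectories into linked-mutation
# cohorts, quantify clonal interference, and reconstruct the Muller
# nesting structure.

suppressPackageStartupMessages(library(evoreseq))

out_dir <- "results/haplotypes"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

traj <- read_trajectories("results/variants/filtered_trajectories.tsv")
m_all <- trajectory_matrix(read_trajectories("results/sim/trajectories.tsv"))
m <- trajectory_matrix(traj)

cs <- clonal_interference_stats(m_all)
message(sprintf(
  "clonal interference: %d mutations observed, %d extinct by the final time point, %d drop > 10%% from their maximum",
  cs$n_total, cs$n_extinct, cs$n_decliners))
utils::write.table(cs$flags, file.path(out_dir, "interference_flags.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

co <- cluster_trajectories(m, distance_threshold = 0.3)
message("clustered ", nrow(m), " trajectories into ",
        length(co$cohorts), " cohorts")

# containment tolerance 0.1: the heterozygous adjustment doubles
# frequencies (and their binomial noise), so near-fixed cohorts jitter by
# ~2 x 2 x sqrt(0.25/500) around each other
md <- build_muller(co, epsilon = 0.1)
n_top <- sum(is.na(md$parent))
message(n_top, " top-level cohort(s); residual ancestral fraction at the ",
        "final time point: ", round(md$residual[length(md$residual)], 3))
export_muller(md, file.path(out_dir, "muller.json"),
              file.path(out_dir, "muller_long.tsv"))
message("wrote cohort structure under ", out_dir)
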