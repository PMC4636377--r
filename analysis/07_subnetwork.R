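#!/usr/bin/env Rscript
# Stage 7: connect the recurrently mutated genes of the simulated
# experiment over a synthetic gene-interaction network with the
# hub-penalizing probabilistic sub-network selection (100-best paths,
# max length 4, search cutoff 0.01, cost 0.25).

suppressPackageStartupMessages(library(evoreseq))

out_dir <- "results/subnetwork"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(20260922)

mut <- utils::read.delim("results/sim/truth_mutations.tsv")
mutated <- unique(mut$gene[!is.na(mut$gene) & mut$gene != ""])
message(length(mutated), " mutated genes enter the network analysis")

# synthetic interactome over the simulated genome's genes: a scale-free-ish
# backbone (a few hubs) plus random typed edges; labelled synthetic
# because the real yeast interactome is an external resource
genes <- utils::read.delim("results/sim/genes.tsv")$gene
n_edges <- 8 * length(genes)
deg_bias <- c(rep(10, 10), rep(1, length(genes) - 10))
edges <- data.frame(
  from = sample(genes, n_edges, TRUE, prob = deg_bias),
  to = sample(genes, n_edges, TRUE, prob = deg_bias),
  type = sample(c("pp", "metabolic", "protein-DNA"), n_edges, TRUE,
                prob = c(0.6, 0.2, 0.2)))
edges <- as_directed_edges(edges)
utils::write.table(data.frame(edges$from, edges$type, edges$to),
                   file.path(out_dir, "synthetic_interactome.sif"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)

pn <- probabilize(edges)
mutated <- intersect(mutated, pn$nodes)
sn <- select_subnetwork(pn, utils::head(mutated, 8), cost = 0.25)

message("selected sub-network: ", nrow(sn$edges), " edges over ",
        nrow(sn$nodes), " genes (",
        sum(sn$nodes$intermediary), " intermediary)")
if (length(sn$unconnected))
  message("unconnected mutated genes: ",
          paste(sn$unconnected, collapse = ", "))

write_sif(sn, file.path(out_dir, "subnetwork.sif"))
utils::write.table(sn$nodes, file.path(out_dir, "nodes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sn$pairs, file.path(out_dir, "pair_paths.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# overlap with a reference set: genes sharing a chromosome with the
# most-hit gene, as a stand-in annotation
ref <- genes[seq(1, length(genes), by = 4)]
ov <- annotate_overlap(sn, pn, ref)
message(sprintf("reference-set overlap: %.0f%% inside vs %.0f%% outside",
                100 * ov$inside, 100 * ov$outside))
message("wrote sub-network under ", out_dir)
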