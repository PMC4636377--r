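#!/usr/bin/env Rscript
# Stage 4: call copy-number variants and aneuploidies from the simulated
# clone depth tracks (500-bp bins, <10-read bins masked, CBS-style
# segmentation at alpha = 1e-9, +-0.25 calling limits) and summarise
# recurrence across clones.

suppressPackageStartupMessages(library(evoreseq))

out_dir <- "results/cnv"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

depth <- read_depth_track("results/sim/depth_tracks.tsv")
lens <- utils::read.delim("results/sim/chrom_lengths.tsv")

seg_list <- lapply(split(depth, depth$clone), function(d) {
  bm <- bin_and_mask(d[, c("chrom", "start", "end", "count")])
  call_segments(segment_log2(log2_ratio(bm)))
})

all_segs <- do.call(rbind, Map(function(s, cl) cbind(clone = cl, s),
                               seg_list, names(seg_list)))
rownames(all_segs) <- NULL
non_neutral <- all_segs[all_segs$call != "neutral", ]
message(nrow(non_neutral), " non-neutral segments across ",
        length(seg_list), " clones")

rec <- summarize_recurrence(seg_list, lens)
if (nrow(rec$aneuploidies)) {
  tab <- table(rec$aneuploidies$chrom, rec$aneuploidies$call)
  message("whole-chromosome aneuploidies (clones affected):")
  print(tab)
} else message("no whole-chromosome aneuploidies called")

utils::write.table(all_segs, file.path(out_dir, "segments.bed"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(rec$recurrence, file.path(out_dir, "recurrence.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(rec$aneuploidies, file.path(out_dir, "aneuploidies.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote CNV calls under ", out_dir)
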