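#!/usr/bin/env Rscript
# Step 4: render the density profile and ratio scan of the detected blocks
# (the diagnostic plot the segmentation is read from): per-contig
# bp-per-kmer on a log scale in density-sorted order, the leading/trailing
# ratio scan below it, and the called block boundaries.

suppressPackageStartupMessages(library(ystrata))

pipedir <- "results/pipeline"
outdir <- "results/figures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

blocks <- utils::read.delim(file.path(pipedir, "blocks.tsv"))
scan <- utils::read.delim(file.path(pipedir, "density_scan.tsv"))
bounds <- which(diff(blocks$block_index) > 0)  # contigs before each boundary

pdf(file.path(outdir, "density_scan.pdf"), width = 8, height = 6)
op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1), mgp = c(2.2, 0.7, 0))
plot(blocks$rank, blocks$bp_per_kmer, log = "y", pch = 19, cex = 0.7,
     col = blocks$block_index + 1,
     xlab = "", ylab = "bp per male-specific k-mer",
     main = "Y contigs sorted by male-specific k-mer density")
abline(v = bounds + 0.5, lty = 2, col = "grey40")
plot(scan$position, scan$ratio, type = "b", pch = 19, cex = 0.6,
     xlab = "contigs passed (density-sorted)",
     ylab = "trailing/leading density ratio")
abline(h = 1.5, lty = 3)
abline(v = bounds, lty = 2, col = "grey40")
par(op)
invisible(dev.off())
message("Wrote ", file.path(outdir, "density_scan.pdf"))
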