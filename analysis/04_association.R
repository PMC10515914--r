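#!/usr/bin/env Rscript
# Differential DNA-speckle association from simulated SON coverage: window
# quantification with background subtraction at 50 and 100 kb, moderated-t
# differential windows, merged decreasing domains, gene classification at
# the padj < 0.01 / > 0.1 thresholds, per-gene SON signal and the decile
# integration against a planted expression response. Outputs under
# results/association/.

library(speckletools)

out <- "results/association"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2024

tr <- gen_track_truth(seed = seed)
tk <- gen_son_tracks(tr, seed = seed)
cs <- c(chr1 = tr$genome_length)

stats <- lapply(c(50000, 100000), function(sz) {
  w <- make_windows(cs, sz)
  sig <- cbind(
    quantify_windows(tk$bins, tk$coverage$control, tk$background$control, w),
    quantify_windows(tk$bins, tk$coverage$treatment, tk$background$treatment,
                     w))
  differential_windows(w, sig, rep(c("control", "treatment"), each = 2))
})
message("Tested windows: ", nrow(stats[[1]]), " (50 kb) + ",
        nrow(stats[[2]]), " (100 kb)")

dom <- merge_domains(stats[[1]], stats[[2]])
message("Merged decreasing domains (padj < 0.01): ", nrow(dom))
print(dom)
write_domains_bed(dom, file.path(out, "decreasing_domains.bed"))

dep <- tr$domains[tr$domains$depleted, ]
mark <- function(d) {
  v <- rep(FALSE, tr$genome_length / 1000)
  for (i in seq_len(nrow(d))) v[(d$start[i] / 1000 + 1):(d$end[i] / 1000)] <- TRUE
  v
}
jac <- sum(mark(dom) & mark(dep)) / sum(mark(dom) | mark(dep))
message(sprintf("Jaccard vs planted depleted domains: %.3f", jac))

# gene annotations tiled across the genome; classification + integration
set.seed(seed)
genes <- data.frame(chrom = "chr1",
                    start = seq(25000, tr$genome_length - 8e4, by = 60000))
genes$end <- genes$start + 4e4
genes$gene_id <- sprintf("G%03d", seq_len(nrow(genes)))

doms_dec <- lapply(stats, function(s) s[s$direction == "decrease", ])
cls <- classify_genes(doms_dec[[1]], doms_dec[[2]], genes)
message("Gene classes: ", paste(names(table(cls$class)), table(cls$class),
                                sep = "=", collapse = ", "))
write.table(cls, file.path(out, "gene_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

son <- per_gene_son_signal(tk$bins, tk$coverage$control,
                           tk$background$control, genes)
# planted expression response: genes in depleted domains lose expression
in_dep <- rep(FALSE, nrow(genes))
for (i in seq_len(nrow(dep)))
  in_dep <- in_dep | (genes$start < dep$end[i] & genes$end > dep$start[i])
lfc <- setNames(ifelse(in_dep, -1.5, 0) + rnorm(nrow(genes), sd = 0.3),
                genes$gene_id)
message(sprintf("Median planted log2FC of associating genes: %.2f",
                median(lfc[cls$gene_id[cls$class == "associating"]])))

nt <- ntile_integration(son, lfc, n = 10)
print(nt$summary)
write.table(nt$summary, file.path(out, "son_decile_integration.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
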