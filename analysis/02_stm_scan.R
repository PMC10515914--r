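#!/usr/bin/env Rscript
# Speckle targeting motif analyses: (1) the best local alignment between
# full-length p53 and HIF-2alpha that motivated the STM definition, (2) STM
# windows in the two vendored factors, (3) recovery of planted STMs from the
# synthetic proteome. Tables land in results/stm/.

library(speckletools)

out <- "results/stm"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

p53 <- read_proteome(system.file("extdata", "p53_P04637.fasta",
                                 package = "speckletools"))
hif <- read_proteome(system.file("extdata", "hif2a_NP_001421.2.fasta",
                                 package = "speckletools"))

message("Best local match, p53 x HIF-2alpha (BLOSUM62, gap 14/4):")
al <- best_local_match(as.character(p53[[1]]), as.character(hif[[1]]))
print(al)
write.table(data.frame(
  n_columns = al$n_columns, score = al$score,
  pct_identity = al$pct_identity, pct_similarity = al$pct_similarity,
  p53_span = paste0(al$startA, "-", al$endA),
  hif2a_span = paste0(al$startB, "-", al$endB)),
  file.path(out, "p53_hif2a_alignment.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

message("STM windows in the vendored factors:")
sc <- scan_proteome(c(p53, hif))
print(sc$windows[, c("protein_id", "start_1based", "window_seq")])
write.table(sc$windows, file.path(out, "fixture_stm_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Planted-proteome recovery:")
pr <- gen_proteome(n_background = 30, n_planted = 10,
                   n_decoys_per_criterion = 2, seed = 2024)
hits <- scan_proteome(pr$proteome)
planted <- pr$truth$protein_id[pr$truth$label == "STM-planted"]
tp <- sum(hits$proteins$protein_id %in% planted)
message(sprintf("  found %d proteins; precision %.2f, recall %.2f",
                nrow(hits$proteins), tp / nrow(hits$proteins),
                tp / length(planted)))
write.table(hits$windows, file.path(out, "synthetic_stm_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
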