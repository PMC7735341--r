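#!/usr/bin/env Rscript
# Matches songs across populations and years two ways: sequence-aware
# LSI over theme strings (full dataset and per-recording median
# strings), and the order-free Dice similarity index on theme presence.
# Exports all three similarity matrices.

suppressPackageStartupMessages(library(songculture))

corpus <- read_corpus("results/corpus")

full <- song_lsi_matrix(corpus$songs, mode = "full")
med <- song_lsi_matrix(corpus$songs, mode = "median")
dsi <- dsi_matrix(corpus$presence)

cat("Song LSI (full):", nrow(full), "song cycles\n")
cat("Song LSI (median):", nrow(med), "recordings\n")
cat("DSI:", nrow(dsi), "recordings\n\n")

cat("Median-string song similarity, first recordings per group:\n")
show <- rownames(med)[!duplicated(sub("_[XYZ]$", "", rownames(med)))]
print(round(med[show, show], 2))

write_similarity_matrix(full, "results/song_lsi_full.csv")
write_similarity_matrix(med, "results/song_lsi_median.csv",
                        long_path = "results/song_lsi_median_long.csv")
write_similarity_matrix(dsi, "results/song_dsi.csv")
cat("\nwrote results/song_lsi_{full,median}.csv, results/song_dsi.csv\n")
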