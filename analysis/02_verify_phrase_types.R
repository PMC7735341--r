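#!/usr/bin/env Rscript
# Checks the phrase-type assignments of the simulated corpus with the
# LSI: within-type similarity must exceed similarity to every other
# type, the criterion used to call a qualitative classification robust.
# Also compares linkage methods by cophenetic correlation, the basis for
# preferring unweighted average linkage (UPGMA).

suppressPackageStartupMessages(library(songculture))

corpus <- read_corpus("results/corpus")

report <- verify_phrase_types(corpus$phrases)
print(report)
cat("\nPer-type summary:\n")
print(report$types)

ccc <- phrase_clustering_ccc(corpus$phrases)
cat("\nCophenetic correlation by linkage (",
    nrow(corpus$phrases), " phrase strings):\n", sep = "")
print(round(ccc, 4))
cat("Average linkage is preferred when its CCC is the highest",
    "(> 0.8 is conventionally good).\n")

dir.create("results", showWarnings = FALSE)
write.csv(report$types, "results/phrase_type_report.csv",
          row.names = FALSE)
write.csv(data.frame(method = names(ccc), ccc = unname(ccc)),
          "results/phrase_ccc.csv", row.names = FALSE)
cat("wrote results/phrase_type_report.csv, results/phrase_ccc.csv\n")
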