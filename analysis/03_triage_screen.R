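#!/usr/bin/env Rscript
# Apply the 3-step triage screen (rare LoF; known pathogenic; rare missense
# at a known pathogenic residue) to the novel (likely) pathogenic variants,
# using the packaged knowledge-base snapshot.

suppressPackageStartupMessages(library(exomereval))
dir.create("results", showWarnings = FALSE)

t1 <- classify_variants(load_fixture("table1"))
kb <- load_fixture("kb")
novel <- t1[t1$gene_classification == "established" &
              t1$tier_points %in% c("P", "LP"), ]
hits <- screen_variants(novel, kb)
write.table(hits[c("family_id", "gene", "cdna", "consequence", "zygosity",
                   "rules_fired")],
            "results/triage_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("novel (likely) pathogenic variants screened: %d\n", nrow(novel)))
cat(sprintf("flagged by the 3-step screen: %d/%d (%d%%)\n", nrow(hits),
            nrow(novel), round_half_up(100 * nrow(hits) / nrow(novel))))
cat("rule breakdown:\n")
print(table(hits$rules_fired))
cat("missed (absent from the knowledge snapshot):",
    paste(setdiff(novel$gene, hits$gene), collapse = ", "), "\n")
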