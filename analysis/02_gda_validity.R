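#!/usr/bin/env Rscript
# Score gene-disease-association validity from the literature-evidence
# tuples printed alongside the re-classified variants.

suppressPackageStartupMessages(library(exomereval))
dir.create("results", showWarnings = FALSE)

t2 <- load_fixture("table2")
res <- classify_gda_table(data.frame(
  gene = t2$gene, n_affected = t2$n_affected_reported,
  n_families = t2$n_families, n_groups = t2$n_groups,
  has_functional = t2$has_functional))
res$printed <- t2$gene_classification
write.table(res, "results/gda_validity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("gene-evidence tuples scored: %d\n", nrow(res)))
print(table(res$tier))
cat(sprintf("agreement with printed classification: %d/%d\n",
            sum(res$tier == res$printed), nrow(res)))
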