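#!/usr/bin/env Rscript
# Stage 4 — two-proteome comparison.
#
# Builds a variant proteome that differs from the stage-1 fixture by a
# single erased planted occurrence, then runs the comparison: the delta
# table localises the missing occurrence to one class-by-category cell, and
# the peptide-set report separates shared from proteome-specific
# (peptide, gene) pairs.

suppressPackageStartupMessages(library(tripepscan))

gen <- make_paper_like_fixture(42L)
prot_a <- gen$proteins
prot_b <- prot_a
victim <- gen$ground_truth$plants[1, ]
i <- match(victim$record_id, prot_b$record_id)
s <- strsplit(prot_b$sequence[i], "")[[1]]
s[(victim$position + 1):(victim$position + 3)] <- c("A", "C", "D")
prot_b$sequence[i] <- paste(s, collapse = "")

hits_a <- scan_proteome(gen$peptides, prot_a)
hits_b <- scan_proteome(gen$peptides, prot_b)
cmp <- compare_proteomes(tabulate_hits(hits_a, prot_a, "category"),
                         tabulate_hits(hits_b, prot_b, "category"),
                         hits_a, hits_b)
dir.create("results/comparison", showWarnings = FALSE, recursive = TRUE)
write_comparison(cmp, "results/comparison/comparison.tsv",
                 "results/comparison/comparison.json")

print(cmp)
cat(sprintf("Erased occurrence: %s in %s (%s) -> delta cell [%s, %s] = %+d\n",
            victim$peptide, victim$gene_symbol, victim$category,
            terminal_class(victim$peptide), victim$category,
            cmp$delta[terminal_class(victim$peptide), victim$category]))
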