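#!/usr/bin/env Rscript
# Stage 3 — digestive releasability of the matched peptides.
#
# Summarises the stage-2 hit annotation: how many matched tripeptides have a
# C-terminus a digestive protease can generate (pepsin, chymotrypsin,
# elastase, prolyl endopeptidase), and how many are fully releasable under
# the minimal two-boundary model.

suppressPackageStartupMessages(library(tripepscan))

hits <- read.table("results/screen/hits.tsv", sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
hits$c_releasable_by[is.na(hits$c_releasable_by)] <- ""

summary_df <- data.frame(
  metric = c("matched peptides",
             "C-releasable by at least one enzyme",
             "N boundary cleavable",
             "fully releasable"),
  count = c(nrow(hits),
            sum(nzchar(hits$c_releasable_by)),
            sum(hits$n_boundary_cleavable),
            sum(hits$fully_releasable)))
summary_df$percent <- round_half_up(100 * summary_df$count / nrow(hits), 1)

dir.create("results", showWarnings = FALSE)
write.table(summary_df, "results/digestion_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary_df, row.names = FALSE)

per_enzyme <- sapply(names(default_enzymes()), function(e)
  sum(grepl(e, hits$c_releasable_by, fixed = TRUE)))
cat("C-releasable hits per enzyme:\n")
print(per_enzyme)
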