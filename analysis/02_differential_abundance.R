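#!/usr/bin/env Rscript
# Stage 2: protein-level quantification.
#
# Equalize-medians normalization, then the three design contrasts that
# feed the corrected interaction effect:
#   main:   BAG3_Biotin vs BioID   (bait proximity + artifacts)
#   biotin: AC16_Biotin vs AC16    (biotin-background correction)
#   oe:     BAG3 vs BioID          (bait over-expression correction)
# Each contrast is a pooled-variance t per protein with BH adjustment
# over testable proteins (>= 2 observed values per group).

library(proxidiff)

inp <- "results/bioid"
mat <- read_matrix(file.path(inp, "intensities_log2.tsv"))
design <- read_design(file.path(inp, "design.tsv"))

norm <- normalize_median(mat)

contrasts <- list(main = c("BAG3_Biotin", "BioID"),
                  biotin = c("AC16_Biotin", "AC16"),
                  oe = c("BAG3", "BioID"))
for (nm in names(contrasts)) {
  gr <- contrasts[[nm]]
  res <- contrast_groups(norm, design, gr[1], gr[2])
  f <- file.path(inp, paste0("contrast_", nm, ".tsv"))
  utils::write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-6s %s vs %s: %d testable, %d with q < 0.05 (%d positive)\n",
              nm, gr[1], gr[2], sum(res$testable),
              sum(res$q < 0.05, na.rm = TRUE),
              sum(res$q < 0.05 & res$log2fc > 0, na.rm = TRUE)))
}
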