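#!/usr/bin/env Rscript
# Stage 3: corrected interaction effects and interactor calls.
#
# corrected = log2FC(BAG3_Biotin vs BioID)
#           - log2FC(AC16_Biotin vs AC16)
#           - log2FC(BAG3 vs BioID)
# A protein is called an interactor when the main contrast is
# BH-significant (q < 0.05) and the corrected effect is positive.
# Because stage 1 wrote ground truth, the call set is scored against
# the planted interactors, and the naive rule (significant main
# contrast with positive raw fold change) is shown for contrast.

library(proxidiff)

inp <- "results/bioid"
read_contrast <- function(nm) {
  utils::read.delim(file.path(inp, paste0("contrast_", nm, ".tsv")))
}
cm <- read_contrast("main")
cb <- read_contrast("biotin")
co <- read_contrast("oe")
truth <- utils::read.delim(file.path(inp, "ground_truth.tsv"))

calls <- call_interactors(cm, cb, co, alpha = 0.05)
utils::write.table(calls, file.path(inp, "interactor_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

interactors <- truth$protein[truth$class == "interactor"]
called <- calls$protein[calls$called]
naive <- cm$feature[cm$testable & !is.na(cm$q) & cm$q < 0.05 & cm$log2fc > 0]

score <- function(set) {
  c(n = length(set),
    sensitivity = round(mean(interactors %in% set), 3),
    fdr = round(if (length(set)) mean(!(set %in% interactors)) else 0, 3))
}
cat("corrected rule:", paste(names(score(called)), score(called),
                             collapse = ", "), "\n")
cat("naive rule:    ", paste(names(score(naive)), score(naive),
                             collapse = ", "), "\n")
m <- merge(calls, truth, by = "protein")
cat("mean corrected effect by class:\n")
print(round(tapply(m$corrected, m$class, mean, na.rm = TRUE), 3))
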