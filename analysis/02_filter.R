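#!/usr/bin/env Rscript
# Stage 2: restrict the corpus to biomedicine.
#
# Applies the inclusion criteria - grant date inside the study window and at
# least one USPC/CPC code matching the allowlist (prefix mode) - and writes
# the filtered corpus plus the per-year audit report.

suppressPackageStartupMessages(library(patentscape))

study <- "results/synthetic_study"
corpus <- read_corpus(file.path(study, "corpus.jsonl"), "records")
criteria <- filter_criteria(date_start = "2000-01-01",
                            date_end = "2002-12-31",
                            cpc_allowlist = "A61K", match_mode = "prefix")
res <- filter_corpus(corpus, criteria)

write_corpus(res$corpus, file.path(study, "filtered.jsonl"), "records")
write_filter_report(res$report, "results/filter_report.csv")

print(res$report)
cat("\nPer-year biomedical share:\n")
print(as.data.frame(res$report$per_year), row.names = FALSE)
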