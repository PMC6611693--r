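#!/usr/bin/env Rscript
# Stage 3: disease annotation and coverage analysis.
#
# Recognizes disease mentions with the lexicon, rolls CUIs up to root
# PheCodes through the ICD-9-CM tables (auditing how many mappings are
# definitive), and computes per-year disease coverage: the share of
# disease-mentioning patent documents that mention each disease.

suppressPackageStartupMessages(library(patentscape))

study <- "results/synthetic_study"
corpus <- read_corpus(file.path(study, "filtered.jsonl"), "records")
lex <- read_lexicon(file.path(study, "lexicon.tsv"))
bundle <- mapping_bundle(
  read_mapping_table(file.path(study, "cui_to_icd9.tsv")),
  read_mapping_table(file.path(study, "icd9_to_phecode.tsv")),
  read_mapping_table(file.path(study, "phecode_to_root.tsv")))

print(mapping_audit(bundle, lex$cui))

ann <- annotate_corpus(corpus, lex, bundle, ambiguity_policy = "all")
write_annotations(ann, "results/annotations.tsv")

years <- setNames(as.integer(format(corpus$grant_date, "%Y")), corpus$doc_id)
mat <- tabulate_disease_year(ann, years)
write_coverage_tables(mat, "results/coverage", k = 8)

cat("\nDiseases covered per year:\n")
print(diseases_covered_per_year(mat))
cat("\nTop diseases by mean coverage:\n")
print(as.data.frame(suppressWarnings(
  top_k_diseases(coverage(mat), 8))), row.names = FALSE)
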