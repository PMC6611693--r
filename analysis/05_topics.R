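#!/usr/bin/env Rscript
# Stage 5: dynamic topic modeling of the biomedical subcorpus.
#
# Preprocesses the filtered corpus (CUI encoding of multiword disease
# concepts, tokenization, stop word removal, lemmatization), builds the
# year-sliced document-term matrix, selects the topic number on a coherence
# grid, fits the dynamic topic model (alpha = 0.01, sigma = 0.005) and
# reports top keywords per slice plus the keyword-drift table.

suppressPackageStartupMessages(library(patentscape))

study <- "results/synthetic_study"
corpus <- read_corpus(file.path(study, "filtered.jsonl"), "records")
lex <- read_lexicon(file.path(study, "lexicon.tsv"))

tok <- preprocess_corpus(corpus, lex)
dtm <- build_matrix(tok, min_df = 2)
cat(sprintf("Document-term matrix: %d docs x %d terms, %d year slices\n",
            nrow(dtm$counts), ncol(dtm$counts), length(dtm$slice_years)))

dir.create("results/topics", showWarnings = FALSE, recursive = TRUE)
write_matrix(dtm, "results/topics/dtm")

sel <- select_topic_number(dtm, grid = c(2, 3, 4, 6),
                           params = dtm_params(n_iter = 40, seed = 42L))
cat("\nCoherence curve (UMass, higher is better):\n")
print(as.data.frame(sel$curve), row.names = FALSE)
cat("Selected K =", sel$best_k, "\n")
write.csv(sel$curve, "results/topics/coherence_curve.csv", row.names = FALSE)

fit <- fit_dtm(dtm, dtm_params(K = sel$best_k, alpha = 0.01, sigma = 0.005,
                               n_iter = 60, seed = 42L))
print(fit)
write_top_words(fit, "results/topics/top_words.csv", n = 10)

cat("\nTop words per topic (final slice):\n")
for (k in seq_len(fit$params$K)) {
  cat(sprintf("  topic %d: %s\n", k,
              paste(top_words(fit, length(fit$beta), k, 8),
                    collapse = " ")))
}

drift <- top_word_drift(fit, n = 10)
write.csv(drift, "results/topics/keyword_drift.csv", row.names = FALSE)
cat("\nKeywords entering/leaving the top-10 across slices:\n")
changed <- drift[drift$n_slices < length(fit$beta), ]
print(as.data.frame(head(changed, 12)), row.names = FALSE)
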