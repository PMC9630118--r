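#!/usr/bin/env Rscript
# Cohort-level unification of the per-sample calls, frequency classes,
# and cohort summaries (NUMTs per individual, size-frequency correlation).

suppressMessages(library(numtatlas))

dir <- "results/cohort"
ref <- read_fasta(file.path(dir, "reference.fa"))
manifest <- read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
calls <- read.table("results/calls.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
calls <- calls[calls$min_support == 2, ]

cohort <- unify_cohort_numts(calls, ref)
cohort <- classify_frequency_and_known(cohort, n_samples = nrow(manifest),
                                       manifest = manifest)
write.table(cohort, "results/cohort_numts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sm <- cohort_summaries(cohort, manifest$sample)
cat(sprintf("%d cohort NUMT loci; %.2f NUMTs per individual (sd %.2f)\n",
            nrow(cohort), sm$mean_numts, sm$sd_numts))
cat("Frequency classes:",
    paste(names(table(cohort$freq_class)), table(cohort$freq_class),
          collapse = ", "), "\n")
if (!is.na(sm$size_frequency$r))
  cat(sprintf("Size-frequency Pearson r = %.3f (p = %.3g, n = %d)\n",
              sm$size_frequency$r, sm$size_frequency$p,
              sm$size_frequency$n))
cat("Cohort table written to results/cohort_numts.tsv\n")
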