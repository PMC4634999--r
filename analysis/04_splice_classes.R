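#!/usr/bin/env Rscript
# Splice-position classification of the cohort's intronic variants and
# allelic-distortion scoring.
#
# Parses every mutation notation in the packaged subject table, classifies
# the splice-type variants relative to splice elements (canonical sites,
# branch region, near-exon, deep intronic), and scores the two reported
# expressed-SNP allele ratios against the GTEx-derived 0.43 threshold.

suppressPackageStartupMessages(library(mosaicscan))

dir.create("results", showWarnings = FALSE)

tab <- load_table1_fixture()
splice <- tab[tab$mutation_type == "splice", ]
cls <- classify_variants(splice$mutation)
cls <- cbind(subject = splice$subject_id, cls)
write.table(cls, "results/04_splice_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Splice-variant classification (18 subjects):\n")
print(cls, row.names = FALSE)
cat("\nClass totals:\n")
print(table(cls$class))
cat("\nThree canonical-site and two deep-intronic variants are fixed by\n")
cat("their offsets; the branch-region vs near-exon split of the remaining\n")
cat("intronic variants depends on the configurable window boundaries.\n\n")

# allelic distortion of expressed heterozygous SNPs (NMD evidence):
# ratios of 0.18 and 0.43 were observed for the two testable subjects
r1 <- allelic_ratio(18, 100)
r2 <- allelic_ratio(43, 100)
ratios <- data.frame(
  case = c("P35-like", "P41-like"),
  ratio = c(r1$ratio, r2$ratio),
  distorted = c(r1$distorted, r2$distorted),
  threshold = 0.43)
write.table(ratios, "results/04_allelic_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Allelic-ratio scoring (strict < 0.43):\n")
print(ratios, row.names = FALSE)
cat("\nA ratio of 0.18 is clearly distorted; 0.43 sits exactly on the\n")
cat("population 1st percentile and is not called distorted under the\n")
cat("strict rule.\nWrote results/04_splice_classes.tsv and results/04_allelic_ratios.tsv\n")
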