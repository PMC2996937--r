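#!/usr/bin/env Rscript
# Stage 1: synthesize the study — genome with planted precursor hairpins,
# annotation blocks, per-base conservation track, adapter-bearing reads,
# and a 3'UTR set with planted conserved/avoided target sites.
# Writes the raw study inputs under results/01_simulate/.

suppressPackageStartupMessages(library(smallmir))

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config()          # the default study conditions
study <- generate_synthetic_study(cfg)

write_fasta(study$genome, file.path(out, "genome.fa"))
write_fastq(study$reads$reads, file.path(out, "reads.fastq"))
write_wig(study$track, file.path(out, "conservation.wig"))
write_fasta(study$utrs$utrs, file.path(out, "utrs.fa"))
ann <- study$truth$annotations
write_bed(data.frame(chrom = ann$chrom, start = ann$start, end = ann$end,
                     strand = ann$strand,
                     name = paste(ann$category, ann$name, sep = "|")),
          file.path(out, "annotations.bed"))
write.table(study$truth$precursors, file.path(out, "truth_precursors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$truth$seeds, file.path(out, "truth_seeds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(cfg[setdiff(names(cfg), "")],
                     file.path(out, "generator_config.json"),
                     auto_unbox = TRUE, pretty = TRUE, force = TRUE)

pr <- study$truth$precursors
cat(sprintf(
  "Synthesized %d nt genome; planted %d novel, %d annotated, %d ncRNA-hosted
precursors and %d decoys; %d raw reads; %d UTRs (%d enriched seeds, %d
avoided seeds planted).\n",
  nchar(study$genome[[1]]),
  sum(pr$kind == "novel"), sum(pr$kind == "annotated"),
  sum(pr$kind == "ncrna"), sum(grepl("^decoy", pr$kind)),
  length(study$reads$reads), length(study$utrs$utrs),
  sum(study$truth$seeds$class == "enriched"),
  sum(study$truth$seeds$class == "avoided")))
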