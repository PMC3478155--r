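#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs with ground truth.
#
# Emulates the study's input universe at desk scale: reference contigs with
# planted miRNA precursors (singletons, one clustered pair, one minus-strand
# plant), a set of "known" mature miRNAs (homolog variants of the planted
# matures at 95% identity), a small-RNA FASTQ library with adapters,
# contaminants and junk reads, 3'UTRs with planted target sites and
# destroy/create SNP plans, and an RT-qPCR Ct table.

suppressPackageStartupMessages(library(mirpipe))
seed <- 42
outdir <- "results/simdata"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

message("## simulating reference contigs with planted precursors")
ref <- make_reference_with_mirnas(n_precursors = 6, contig_length = 600,
                                  seed = seed, n_clusters = 1, cluster_size = 2,
                                  cluster_gap = 100,
                                  minus_strand = c(FALSE, FALSE, FALSE, FALSE,
                                                   FALSE, TRUE))
refs_df <- data.frame(id = names(ref$references),
                      sequence = unname(ref$references),
                      description = "", alphabet = "DNA")
write_sequences(refs_df, file.path(outdir, "contigs.fa"))
write.table(ref$truth, file.path(outdir, "precursor_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("   ", length(ref$references), " contigs, ", nrow(ref$truth),
        " planted precursors")

message("## deriving a 'known animal miRNA' set (homologs at 95% identity)")
known <- vapply(seq_len(nrow(ref$truth)), function(i) {
  mutate_homolog(ref$truth$mature[i], 0.95, seed = seed + i)$sequence
}, character(1))
# the first four plants get a known homolog; the rest stay species-specific
known_df <- data.frame(id = paste0("ani-mir-", seq_len(4)),
                       sequence = known[1:4], description = "known mature",
                       alphabet = "RNA")
write_sequences(known_df, file.path(outdir, "known_matures.fa"))

message("## simulating the small-RNA library")
contam <- list(
  rRNA = c(rrna1 = mirpipe:::.with_seed(seed + 101, random_rna(400))),
  tRNA = c(trna1 = mirpipe:::.with_seed(seed + 102, random_rna(90))),
  snRNA = c(snrna1 = mirpipe:::.with_seed(seed + 103, random_rna(150))),
  "repeat" = c(rep1 = mirpipe:::.with_seed(seed + 104, random_rna(300))))
for (cls in names(contam)) {
  df <- data.frame(id = names(contam[[cls]]), sequence = unname(contam[[cls]]),
                   description = cls, alphabet = "DNA")
  write_sequences(df, file.path(outdir, paste0("contam_", sub("repeat", "rep", cls), ".fa")))
}
lib <- simulate_sreads(ref$truth, depth = 25, star_depth = 3, isomir_per = 2,
                       mor_per = 1, n_contaminant = 60, n_polyA = 30,
                       n_short = 15, n_adapter5 = 10, n_lowq = 10,
                       contaminants = contam, seed = seed + 2)
write_sequences(lib$reads, file.path(outdir, "srna_reads.fq"), format = "fastq")
write.table(lib$truth, file.path(outdir, "read_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("   ", nrow(lib$reads), " reads (",
        sum(lib$truth$class %in% c("mature", "star", "isomir", "mor")),
        " precursor-derived)")

message("## simulating 3'UTRs with planted sites and SNP plans")
mir_for_utrs <- ref$truth$mature[1]
fx_plain <- make_utr_with_sites(mir_for_utrs, "8mer", seed = seed + 3,
                                mrna_id = "mrna_site")
fx_destroy <- make_utr_with_sites(mir_for_utrs, "8mer", snp_plan = "destroy",
                                  seed = seed + 4, mrna_id = "mrna_loss")
fx_create <- make_utr_with_sites(mir_for_utrs, "8mer", snp_plan = "create",
                                 seed = seed + 5, mrna_id = "mrna_gain")
utrs <- data.frame(
  id = c(fx_plain$utr$id, fx_destroy$utr$id, fx_create$utr$id),
  sequence = c(fx_plain$utr$sequence, fx_destroy$utr$sequence,
               fx_create$utr$sequence),
  description = "synthetic 3'UTR", alphabet = "DNA")
write_sequences(utrs, file.path(outdir, "utrs.fa"))
snps <- rbind(fx_destroy$snp, fx_create$snp)
snps$plan <- c("destroy", "create")
write.table(snps, file.path(outdir, "utr_snps.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message("## simulating precursor SNPs (one per region class)")
hp <- ref$truth[1, ]
ann <- annotate_regions(hp$structure, c(hp$mature_start, hp$mature_end))
pick <- function(region) {
  pos <- which(vapply(seq_len(nchar(hp$precursor)), function(p) {
    classify_snp(p, ann) == region
  }, logical(1)))[1]
  ref_b <- substring(hp$precursor, pos, pos)
  alt_b <- setdiff(c("A", "C", "G", "U"), ref_b)[1]
  data.frame(reference_id = hp$name, position = pos, ref_allele = ref_b,
             alt_allele = alt_b, planted_region = region)
}
pre_snps <- do.call(rbind, lapply(c("mature", "stem", "loop", "anti-stem"), pick))
write.table(pre_snps, file.path(outdir, "precursor_snps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("## simulating an RT-qPCR Ct table (5 developmental stages)")
set.seed(seed + 6)
stages <- c("oocyte_0h", "embryo_72hpf", "larva_1dph", "larva_5dph", "larva_10dph")
genes <- c(ref$truth$name[1:4], "U6")
ct <- expand.grid(sample = stages, gene = genes, stringsAsFactors = FALSE)
ct$ct <- round(runif(nrow(ct), 18, 30), 2)
ct$ct[ct$gene == "U6"] <- round(runif(length(stages), 15, 15.5), 2)
write.table(ct, file.path(outdir, "ct_values.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message("done: inputs under ", outdir)
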