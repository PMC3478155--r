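#!/usr/bin/env Rscript
# Step 2: discover miRNAs by both arms and merge the catalogs.
#
# Homology arm: known matures aligned at 90% identity, candidates excised
# with 60 nt flanks, folded, six hairpin criteria applied. Sequencing arm:
# reads cleaned (adapters, poly(A), quality, length), contaminants
# annotated (rRNA > tRNA > snRNA > repeat), read stacks mapped and folded.
# Outputs: unified catalog (TSV + GFF3), read accounting (JSON), isomiR and
# moRNA tables.

suppressPackageStartupMessages({library(mirpipe); library(jsonlite)})
ind <- "results/simdata"
outdir <- "results"
stopifnot(file.exists(file.path(ind, "contigs.fa")))

refs <- read_sequences(file.path(ind, "contigs.fa"))
known <- read_sequences(file.path(ind, "known_matures.fa"))
truth <- read.delim(file.path(ind, "precursor_truth.tsv"))

message("## homology arm: ", nrow(known), " known matures vs ",
        nrow(refs), " contigs")
hom <- discover_homology(known, refs)
message("   ", nrow(hom), " precursors pass the six hairpin criteria")

message("## sequencing arm: cleaning reads")
reads <- read_sequences(file.path(ind, "srna_reads.fq"))
cl <- clean_reads(reads, adapter_3p = "UCGUAUGCCGUCUUCUGCUUG",
                  adapter_5p = "GUUCAGAGUUCUACAGUCCGACGAUC")
contam <- list(rRNA = file.path(ind, "contam_rRNA.fa"),
               tRNA = file.path(ind, "contam_tRNA.fa"),
               snRNA = file.path(ind, "contam_snRNA.fa"),
               "repeat" = file.path(ind, "contam_rep.fa"))
ann <- annotate_contaminants(cl$reads, contam, raw_count = cl$accounting$raw_count)
print(ann$accounting)
un <- ann$reads[ann$reads$annotation_class == "unannotated", ]

message("## sequencing arm: locus discovery on ", nrow(un), " unique sequences")
disc <- discover_from_reads(un, refs)
message("   ", nrow(disc$catalog), " read-supported precursors (",
        nrow(disc$rejected), " loci rejected)")

message("## merging catalogs")
merged <- merge_catalogs(hom, disc$catalog, known_matures = known)
cat_df <- merged$catalog
message("   catalog: ", merged$summary[["total"]], " miRNAs (",
        merged$summary[["conserved"]], " conserved, ",
        merged$summary[["specific"]], " specific); planted truth: ",
        nrow(truth))

write.table(cat_df, file.path(outdir, "catalog.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
gff <- data.frame(reference_id = cat_df$reference_id, start = cat_df$start,
                  end = cat_df$end, strand = cat_df$strand, type = "pre_miRNA",
                  id = make.unique(cat_df$name), stringsAsFactors = FALSE)
write_annotation(gff, file.path(outdir, "catalog.gff3"), format = "gff3")
acc <- ann$accounting
write_json(list(raw = acc$raw_count, cleaned = acc$cleaned_count,
                pct_cleaned = acc$pct_cleaned,
                contaminants = as.list(acc$contaminants),
                remaining = acc$remaining_count),
           file.path(outdir, "read_accounting.json"), auto_unbox = TRUE)

message("## isomiRs and moRNAs")
iso <- detect_isomiRs(ann$reads, cat_df)
write.table(iso, file.path(outdir, "isomirs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
mor_all <- do.call(rbind, lapply(seq_len(nrow(cat_df)), function(i) {
  mo <- detect_moRNAs(ann$reads, cat_df$precursor_sequence[i],
                      c(cat_df$mature_start[i], cat_df$mature_end[i]))
  if (nrow(mo)) mo$name <- cat_df$name[i]
  mo
}))
if (is.null(mor_all)) mor_all <- data.frame()
write.table(mor_all, file.path(outdir, "mornas.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("   ", nrow(iso), " isomiR records, ",
        if (nrow(mor_all)) nrow(mor_all) else 0, " moRNA candidates")
message("done: catalog under ", outdir)
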