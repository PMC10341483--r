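#!/usr/bin/env Rscript
# Step 3 — CRE elements: promoter windows, motif-to-gene assignment, and
# location classification of differentially acetylated regions.
#
# Promoter windows span 1000 bp on each side of the TSS (2001 bp, strand
# aware); motifs are assigned to every gene with a TSS within 3 kb of the
# motif midpoint; differentially acetylated CRE regions are classified as
# promoter / gene body / downstream / intergenic by midpoint precedence.

library(regucircuit)

sim_dir <- "results/sim"
diff_dir <- "results/differential"
out_dir <- "results/cre"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ann <- read_gtf(file.path(sim_dir, "genes.gtf"))
motifs <- read_bed(file.path(sim_dir, "motifs.bed"))

windows <- build_promoter_windows(ann, 1000L)
write_promoter_gtf(windows, file.path(out_dir, "promoters.gtf"))
cat(sprintf("promoter windows: %d, width %s bp\n", nrow(windows),
            paste(unique(windows$end - windows$start), collapse = "/")))

assignments <- assign_cre_genes(motifs, ann, max_distance = 3000L)
write.table(assignments, file.path(out_dir, "cre_gene_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("motif occurrences: %d; assigned to >=1 gene: %d; (motif, gene) pairs: %d\n",
            nrow(motifs), length(unique(assignments$motif_id)), nrow(assignments)))

locations <- classify_location(motifs, ann, windows)
diff_cre <- read.table(file.path(diff_dir, "diff_cre_6wk.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
merged <- cre_acetylation_table(assignments, diff_cre, locations)
write.table(merged$table, file.path(out_dir, "cre_acetylation_6wk.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(merged$gene_flags, file.path(out_dir, "cre_gene_flags_6wk.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

da <- merged$table[merged$table$acetyl_status != "ns" &
                     merged$table$acetyl_status != "absent", ]
cat(sprintf("differentially acetylated assigned CRE regions (6wk): %d\n",
            length(unique(da$motif_id))))
print(table(location = da$location, status = da$acetyl_status))
cat(sprintf("genes reachable from a differentially acetylated CRE: %d\n",
            sum(merged$gene_flags$cre_up | merged$gene_flags$cre_down)))
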