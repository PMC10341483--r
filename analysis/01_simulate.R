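#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Emits a toy genome annotation, CRE motif occurrences, NB count matrices for
# genes / promoter windows / CRE regions in a 2 (genotype) x 2 (time) design
# with 3 replicates per cell, a general TF->target network with a planted
# six-TF mutually regulating core, and the physical interactions among the
# core members. All downstream steps read these files, exactly as a real-data
# run would read its own inputs.

library(regucircuit)

outdir <- "results/sim"
cfg <- sim_config(seed = 20260925L, mutant_only_mr = TRUE)
sim <- write_synthetic_study(cfg, outdir)

cat("Synthetic study written to", outdir, "\n")
cat(sprintf("  genes: %d (%d TFs), chromosomes: %s\n", cfg$n_genes, cfg$n_tfs,
            paste(names(cfg$chrom_sizes), collapse = ", ")))
cat(sprintf("  motif occurrences: %d (%d planted near a TSS)\n",
            nrow(sim$motifs), nrow(sim$truth$cre_gene_map)))
cat(sprintf("  network: %d edges over %d nodes; planted core: %s\n",
            nrow(sim$network$edges), nrow(sim$network$nodes),
            paste(sim$truth$planted_core, collapse = ", ")))
cat(sprintf("  planted DE genes: %d; planted acetylation effects: %d promoters, %d CRE regions\n",
            nrow(sim$truth$de_genes), nrow(sim$truth$diff_acetyl_promoters),
            nrow(sim$truth$diff_acetyl_cres)))
cat(sprintf("  core TF silenced in control (mutant-only MR design): %s\n",
            paste(sim$truth$mutant_only_mr, collapse = ", ")))
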