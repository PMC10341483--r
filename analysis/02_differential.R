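#!/usr/bin/env Rscript
# Step 2 — differential expression and differential acetylation.
#
# NB Wald tests per time point (mutant vs control) plus the two-factor
# genotype + time design for gene expression; the same test applied to
# promoter-window and CRE-region acetylation counts, called on raw p < 0.05
# as is conventional for the acetylation analyses. Expression calls use
# BH-adjusted p < 0.05.

library(regucircuit)

sim_dir <- "results/sim"
out_dir <- "results/differential"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genes <- read_counts(file.path(sim_dir, "counts_genes.tsv"),
                     file.path(sim_dir, "samples.tsv"))
prom <- read_counts(file.path(sim_dir, "counts_promoters.tsv"),
                    file.path(sim_dir, "samples.tsv"))
cre <- read_counts(file.path(sim_dir, "counts_cre.tsv"),
                   file.path(sim_dir, "samples.tsv"))

expr_cfg <- diff_config(alpha = 0.05, use_adjusted = TRUE)
acetyl_cfg <- diff_config(alpha = 0.05, use_adjusted = FALSE)

de <- list()
for (tp in c("4wk", "6wk")) {
  de[[tp]] <- nb_test(subset_time(genes, tp), expr_cfg)
  write.table(de[[tp]], file.path(out_dir, paste0("de_genes_", tp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d DE genes (%d up / %d down in mutant)\n", tp,
              sum(de[[tp]]$status != "ns"), sum(de[[tp]]$status == "up"),
              sum(de[[tp]]$status == "down")))
}
shared <- intersect(de$`4wk`$feature_id[de$`4wk`$status != "ns"],
                    de$`6wk`$feature_id[de$`6wk`$status != "ns"])
cat(sprintf("DE genes shared between time points: %d (%s)\n", length(shared),
            paste(utils::head(shared, 6), collapse = ", ")))

de2 <- nb_test_two_factor(genes, expr_cfg)
write.table(de2, file.path(out_dir, "de_genes_two_factor.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("two-factor (genotype + time): %d genes with a genotype effect\n",
            sum(de2$status != "ns")))

for (tp in c("4wk", "6wk")) {
  dp <- nb_test(subset_time(prom, tp), acetyl_cfg)
  write.table(dp, file.path(out_dir, paste0("diff_promoters_", tp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dc <- nb_test(subset_time(cre, tp), acetyl_cfg)
  write.table(dc, file.path(out_dir, paste0("diff_cre_", tp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s acetylation: %d promoters (%d up / %d down), %d CRE regions (%d up / %d down)\n",
              tp, sum(dp$status != "ns"), sum(dp$status == "up"),
              sum(dp$status == "down"), sum(dc$status != "ns"),
              sum(dc$status == "up"), sum(dc$status == "down")))
}
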