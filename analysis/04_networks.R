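#!/usr/bin/env Rscript
# Step 4 — condition-specific regulatory networks.
#
# The general TF->target network is contextualized per condition by keeping
# only edges whose source TF is expressed (mean normalized count >= 10 in
# that condition's samples at 6 weeks), then annotated with DE status and
# promoter/CRE acetylation status. Networks are compared in the usual
# total/unique bookkeeping and exported to GraphML for visualization.

library(regucircuit)

sim_dir <- "results/sim"
diff_dir <- "results/differential"
cre_dir <- "results/cre"
out_dir <- "results/networks"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

general <- load_general_grn(file.path(sim_dir, "grn.tsv"))
genes <- read_counts(file.path(sim_dir, "counts_genes.tsv"),
                     file.path(sim_dir, "samples.tsv"))
cm6 <- subset_time(genes, "6wk")
de6 <- read.table(file.path(diff_dir, "de_genes_6wk.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
prom6 <- read.table(file.path(diff_dir, "diff_promoters_6wk.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
flags <- read.table(file.path(cre_dir, "cre_gene_flags_6wk.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

nets <- list()
for (cond in c("control", "mutant")) {
  expressed <- expressed_genes(cm6, condition = cond, threshold = 10)
  net <- contextualize(general, expressed)
  net <- annotate_network(net, de = de6, prom_acetyl = prom6, cre_flags = flags)
  nets[[cond]] <- net
  write_graphml(net, file.path(out_dir, paste0("network_", cond, "_6wk.graphml")))
  cat(sprintf("%s network (6wk): %d nodes (%d TFs), %d edges; DE nodes: %d\n",
              cond, nrow(net$nodes), sum(net$nodes$is_tf), nrow(net$edges),
              sum(net$nodes$de_status %in% c("up", "down"))))
}

stats <- compare_networks(nets$control, nets$mutant, c("control_6wk", "mutant_6wk"))
write.table(cbind(network = rownames(stats), stats),
            file.path(out_dir, "network_stats_6wk.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\ntotal / unique bookkeeping:\n")
print(stats)

# the planted-core cascade: the core TFs and everything they directly drive
core_tfs <- grep("^TF00[1-6]$", nets$mutant$nodes$gene_id, value = TRUE)
cascade <- cre_regulatory_subnetwork(nets$mutant, core_tfs)
write_graphml(cascade, file.path(out_dir, "core_cascade_mutant_6wk.graphml"))
cat(sprintf("\ncore regulatory cascade (mutant): %d nodes, %d edges\n",
            nrow(cascade$nodes), nrow(cascade$edges)))
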