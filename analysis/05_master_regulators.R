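#!/usr/bin/env Rscript
# Step 5 — master-regulator inference and condition contrast.
#
# For the 6-week DE genes: take first and second upstream neighbors in each
# condition's network, prune the neighborhood by iterative minimal-out-degree
# deletion until a deletion would disconnect it, and validate the surviving
# TF candidates by mutual regulation AND physical interaction. The validated
# sets are contrasted between control and mutant.

library(regucircuit)

sim_dir <- "results/sim"
diff_dir <- "results/differential"
out_dir <- "results/master_regulators"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

general <- load_general_grn(file.path(sim_dir, "grn.tsv"))
ppi <- read_ppi(file.path(sim_dir, "ppi.tsv"))
genes <- read_counts(file.path(sim_dir, "counts_genes.tsv"),
                     file.path(sim_dir, "samples.tsv"))
cm6 <- subset_time(genes, "6wk")
de6 <- read.table(file.path(diff_dir, "de_genes_6wk.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
de_genes <- de6$feature_id[de6$status != "ns"]
cat(sprintf("seeding with %d DE genes at 6wk\n", length(de_genes)))

reports <- list()
for (cond in c("control", "mutant")) {
  expressed <- expressed_genes(cm6, condition = cond, threshold = 10)
  net <- contextualize(general, expressed)
  rep_ <- infer_mrs(net, de_genes, ppi, depth = 2L, rule = "both")
  reports[[cond]] <- rep_
  write_mr_report(rep_, file.path(out_dir, paste0("mr_", cond, "_6wk.tsv")),
                  file.path(out_dir, paste0("mr_trace_", cond, "_6wk.tsv")))
  cat(sprintf("%s: neighborhood %d nodes, %d deletions, %d candidates, %d validated (%s)\n",
              cond, length(rep_$neighborhood_nodes), nrow(rep_$deletion_trace),
              length(rep_$core_candidates), length(rep_$validated_mrs),
              paste(rep_$validated_mrs, collapse = ", ")))
}

ctr <- mr_condition_contrast(reports$control, reports$mutant)
contrast <- data.frame(
  set = c(rep("shared", length(ctr$shared)),
          rep("control_only", length(ctr$control_only)),
          rep("mutant_only", length(ctr$mutant_only))),
  gene_id = c(ctr$shared, ctr$control_only, ctr$mutant_only),
  stringsAsFactors = FALSE)
write.table(contrast, file.path(out_dir, "mr_contrast_6wk.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nshared MRs: %d; control-only: %d; mutant-only: %d (%s)\n",
            length(ctr$shared), length(ctr$control_only),
            length(ctr$mutant_only), paste(ctr$mutant_only, collapse = ", ")))
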