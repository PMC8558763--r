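#!/usr/bin/env Rscript
# Generate the three synthetic allelic datasets used by the downstream
# analyses, with full ground truth, and write them as plain-text files
# under results/data/. All effect sizes are the study conditions baked
# into the generator presets (Xa accessibility fold 1.33, expression
# fold 1.35, 5-class Xi reactivation schedule, 7-category chromatin
# opening schedule).

suppressPackageStartupMessages(library(xdosage))
seed <- 2024
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("## ATAC reprogramming timepoints (d0 .. iPSC)")
atac <- simulate_atac_timepoints(atac_config("mef_female"), seed = seed)
write_allelic_matrix(atac$matrix, file.path(out, "atac"))
utils::write.table(atac$truth, file.path(out, "atac_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("  ", nrow(atac$matrix$counts_mus), " regions x ",
        ncol(atac$matrix$counts_mus), " samples; Xa enhancement ",
        "multipliers per timepoint:")
print(round(atac$xa_multiplier, 3))

message("## scRNA-seq reprogramming trajectory")
sc <- simulate_reprogramming_scrna(scrna_config("reprogramming"),
                                   seed = seed + 1)
write_allelic_matrix(sc$matrix, file.path(out, "scrna"))
write_pseudotime(sc$pseudotime, file.path(out, "scrna_pseudotime.tsv"))
utils::write.table(sc$truth$genes, file.path(out, "scrna_gene_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("  ", nrow(sc$matrix$counts_mus), " genes x ",
        ncol(sc$matrix$counts_mus), " cells; Xa k_on multiplier = ",
        round(sc$truth$xa_kon_multiplier, 3))
message("  kinetic classes: ",
        paste(names(table(sc$truth$genes$klass)),
              table(sc$truth$genes$klass), collapse = ", "))

message("## XX / XO iPSCs")
xo <- simulate_xo_ipscs(scrna_config("xo_ipsc", ksyn_meanlog = log(600)),
                        seed = seed + 2)
write_allelic_matrix(xo$matrix, file.path(out, "xo"))
utils::write.table(xo$truth$cells, file.path(out, "xo_cell_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("  X states: ",
        paste(names(table(xo$truth$cells$x_state)),
              table(xo$truth$cells$x_state), collapse = ", "))
message("done: plain-text datasets under ", out)
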