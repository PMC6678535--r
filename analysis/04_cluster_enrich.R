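#!/usr/bin/env Rscript

# Cross-sample structure. (a) Hierarchical clustering (Pearson distance,
# Ward) of two simulated genetic backgrounds, each with a parental and a
# resistant member: background aberrations dominate acquired ones, so the
# tree should group by background, not by resistance status. (b) A
# hypergeometric cytoband enrichment of the genes in the acquired regions
# of the differential run.

suppressPackageStartupMessages(library(cnadiff))
out <- "results/structure"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 4100

design <- generate_design(20000, seed = seed)
prep <- function(ps) gc_correct(compute_log2_profile(dye_normalize(ps)))
profiles <- list()
for (bg in 1:2) {
  cna <- random_cna_spec(design, n_shared = 10, n_acquired = 2,
                         min_probes = 400, max_probes = 800,
                         shared_amplitudes = c(-1, 1),
                         acquired_amplitudes = c(-0.8, 0.8),
                         seed = seed + bg)
  sim <- simulate_pair(design, cna, noise_model(probe_noise_sd = 0.25),
                       seed = seed + 10 + bg,
                       sample_ids = paste0(c("parental_bg", "resistant_bg"), bg))
  profiles <- c(profiles, list(prep(sim$parental), prep(sim$resistant)))
}
cl <- cluster_profiles(profiles)
write_newick(cl, file.path(out, "profiles.nwk"))
grp <- cut_clusters(cl, 2)
cat("2-cluster cut:\n")
print(grp)
cat("Grouped by background:",
    grp[1] == grp[2] && grp[3] == grp[4] && grp[1] != grp[3], "\n")

# enrichment: genes overlapping the acquired regions of the paired run,
# against all annotated genes
genes <- read_annotation_bed("results/sim/genes.bed", "gene")
bands <- read_annotation_bed("results/sim/cytobands.bed", "cytoband")
ann <- genome_annotation(cytobands = bands, genes = genes)
truth <- read.delim("results/sim/truth.tsv")
acq <- truth[truth$scope == "resistant_only", ]
query <- unique(unlist(lapply(seq_len(nrow(acq)), function(i) {
  annotation_query(ann, acq$chrom[i], acq$start[i], acq$end[i], "gene")
})))
enr <- cytoband_enrichment(query, genes$name, ann)
write.table(enr, file.path(out, "cytoband_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nTop enriched cytobands for", length(query), "acquired-region genes:\n")
print(head(enr, 5))
cat("Wrote", out, "\n")
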