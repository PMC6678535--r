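#!/usr/bin/env Rscript

# Simulate the study's raw materials with known ground truth:
# a 180K-probe array design, one parental/resistant hybridization pair
# (5 shared + 3 acquired CNAs, realistic GC/dye biases and noise),
# cytoband and gene annotation fixtures, and dose-response plates for the
# parental line, the resistant line, and the resistant line under a
# resistance-reverting co-treatment.

suppressPackageStartupMessages(library(cnadiff))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260926

design <- generate_design(180000, seed = seed)
cna <- random_cna_spec(design, n_shared = 5, n_acquired = 3,
                       min_probes = 100, max_probes = 200,
                       acquired_amplitudes = c(-4.7, -3.2, -1, 1, 3.2, 4.7),
                       seed = seed + 1)
sim <- simulate_pair(design, cna, noise_model(probe_noise_sd = 0.25),
                     seed = seed + 2)

write_probe_table(sim$parental, file.path(out, "parental.tsv"))
write_probe_table(sim$resistant, file.path(out, "resistant.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# cytoband fixture (synthetic banding; 8 bands per chromosome)
bands <- synthetic_cytobands(design)
write.table(bands, file.path(out, "cytobands.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

# synthetic gene fixture: 2,000 uniformly placed labeled genes
set.seed(seed + 3)
lens <- hg19_chrom_lengths()
gchrom <- names(lens)[sample.int(length(lens), 2000, replace = TRUE,
                                 prob = lens / sum(lens))]
gstart <- floor(runif(2000, 0, lens[gchrom] - 2e5))
genes <- data.frame(chrom = gchrom, start = gstart,
                    end = gstart + round(runif(2000, 2e4, 2e5)),
                    name = sprintf("GENE%04d", 1:2000))
genes <- genes[order(match(genes$chrom, names(lens)), genes$start), ]
write.table(genes, file.path(out, "genes.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

# dose-response plates (viability fractions, 3 replicates, noise SD 0.05)
doses <- 10^seq(-3, 1.5, length.out = 9)
plates <- list(
  list(id = "parental", truth = list(top = 1, bottom = 0.05, hill = 1.2,
                                     ic50 = 0.06)),
  list(id = "resistant", truth = list(top = 1, bottom = 0.05, hill = 1.2,
                                      ic50 = 8)),
  list(id = "resistant_verapamil",
       truth = list(top = 1, bottom = 0.05, hill = 1.2, ic50 = 0.5))
)
rows <- lapply(seq_along(plates), function(i) {
  d <- simulate_dose_response(plates[[i]]$truth, doses, replicates = 3,
                              noise_sd = 0.05, seed = seed + 10 + i,
                              compound = "DOXO", sample_id = plates[[i]]$id)
  data.frame(compound = d$compound, sample_id = d$sample_id,
             dose_uM = d$data$dose, viability = d$data$response,
             replicate = d$data$replicate)
})
write.table(do.call(rbind, rows), file.path(out, "dose_response.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated pair with ground truth:\n")
print(sim$truth)
cat("\nWrote", out, "\n")
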