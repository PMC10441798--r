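#!/usr/bin/env Rscript
# Generates the synthetic input bundle every later stage consumes:
# toy stoichiometric networks (JSON + SBML), a homology hit table with
# planted orthologs, a phenotype plate with a 10% call-error rate, a
# kinetic batch time course, and genome/proteome FASTA files. All
# generators are seeded; ground truth is recorded alongside.

suppressMessages(library(gemcurator))
seed <- 42
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

toy <- gen_toy_network(seed, yields = c(0.5, 0.8), uptake = 10,
                       plant_dead_end = TRUE)
write_model(toy$model, file.path(out, "toy_network.json"))
write_model(toy$model, file.path(out, "toy_network.xml"))
cat("toy network:", length(toy$model$reactions), "reactions,",
    "optimal growth", toy$truth$mu_optimal, "1/h by construction\n")

leaky <- gen_toy_network(seed, yields = c(0.5, 0.8),
                         plant_energy_cycle = TRUE)
write_model(leaky$model, file.path(out, "toy_network_leaky.json"))

template_gprs <- list(r1 = "tA and tB", r2 = "tC", r3 = "tD or tE",
                      r4 = "tF", r5 = "tG and tH")
reference <- list(r1 = c("q1", "q2"), r2 = "q3", r3 = c("q4", "q5"),
                  r4 = "q6", r5 = c("q7", "q8"))
hom <- gen_homology_table(seed, template_gprs, reference,
                          n_decoys = 60, decoys_above = 6)
utils::write.table(
  data.frame(qseqid = hom$hits$query, sseqid = hom$hits$subject,
             pident = hom$hits$identity_pct,
             length = hom$hits$alignment_length,
             evalue = hom$hits$e_value,
             qcovs = hom$hits$query_coverage_pct),
  file.path(out, "homology_hits.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
saveRDS_free <- function(x, path) {   # plain-text persistence only
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE), path)
}
saveRDS_free(list(template_gprs = template_gprs,
                  reference = reference), file.path(out, "gprs.json"))
cat("homology table:", nrow(hom$hits), "hits (",
    sum(lengths(reference)), "planted,",
    length(hom$decoys_above_threshold), "decoys above threshold )\n")

pm <- gen_plate_model(seed, n_substrates = 12, n_usable = 7)
write_model(pm$model, file.path(out, "plate_model.json"))
pl <- gen_phenotype_plate(pm$model, seed, p = 0.1, n_wells = 500)
utils::write.table(pl$plate, file.path(out, "phenotype_plate.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("phenotype plate: 500 wells over 12 substrates,",
    sum(pl$flips), "calls flipped (planted error rate 0.1)\n")

ser <- gen_kinetic_series(seed, v = 5, Y = 0.05, X0 = 0.01, S0 = 20,
                          sigma = 0.01)
utils::write.table(ser$data, file.path(out, "kinetic_series.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("kinetic series:", nrow(ser$data), "exponential-phase points,",
    "true v_max 5 mmol/gDW/h, depletion at",
    round(ser$truth$t_deplete, 2), "h\n")

Biostrings::writeXStringSet(
  gen_sequences(seed, "protein", length = 2e4),
  file.path(out, "proteome_synthetic.faa"))
Biostrings::writeXStringSet(
  gen_sequences(seed, "dna", length = 2e4, gc_content = 0.65),
  file.path(out, "genome_synthetic.fna"))
cat("sequences: synthetic proteome (20 kaa) and genome (20 kb, GC 0.65)\n")
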