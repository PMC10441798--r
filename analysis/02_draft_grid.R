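#!/usr/bin/env Rscript
# Homology-transfer grid study: evaluates all 384 cutoff combinations
# (8 e-values x 6 alignment lengths x 8 identity thresholds) of the
# draft GPR transfer against the curated reference, reproducing the
# relaxed-vs-strict trade-off between true and false positive calls.

suppressMessages(library(gemcurator))
inp <- "results/inputs"
hits <- read_hit_table(file.path(inp, "homology_hits.tsv"))
gprs <- jsonlite::read_json(file.path(inp, "gprs.json"),
                            simplifyVector = TRUE)
template_gprs <- as.list(gprs$template_gprs)
reference <- lapply(gprs$reference, unlist)

tab <- grid_search(hits, template_gprs, reference)
utils::write.table(tab, "results/draft_grid.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("grid:", nrow(tab), "draft evaluations written to results/draft_grid.tsv\n")

strict <- tab[tab$max_e_value == min(tab$max_e_value) &
                tab$min_length == max(tab$min_length) &
                tab$min_identity_pct == max(tab$min_identity_pct), ]
relaxed <- tab[tab$max_e_value == max(tab$max_e_value) &
                 tab$min_length == min(tab$min_length) &
                 tab$min_identity_pct == min(tab$min_identity_pct), ]
cat(sprintf("strictest cutoffs (e<=%g, len>=%g, id>=%g%%): TP %d, FP %d, FN %d\n",
            strict$max_e_value, strict$min_length,
            strict$min_identity_pct, strict$tp_accumulative,
            strict$fp_accumulative, strict$fn_accumulative))
cat(sprintf("most relaxed (e<=%g, len>=%g, id>=%g%%): TP %d, FP %d, FN %d\n",
            relaxed$max_e_value, relaxed$min_length,
            relaxed$min_identity_pct, relaxed$tp_accumulative,
            relaxed$fp_accumulative, relaxed$fn_accumulative))
best <- tab[order(tab$fn_accumulative, tab$unique_fp,
                  -tab$tp_accumulative), ][1, ]
cat(sprintf("a best row: e<=%g, len>=%g, id>=%g%% -> TP %d, unique FP %d, FN %d\n",
            best$max_e_value, best$min_length, best$min_identity_pct,
            best$tp_accumulative, best$unique_fp,
            best$fn_accumulative))
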