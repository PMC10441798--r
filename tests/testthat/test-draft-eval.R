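hit_row <- function(query, subject, e, len, ident, cov = NA) {
  data.frame(query = query, subject = subject, identity_pct = ident,
             alignment_length = as.integer(len), e_value = e,
             query_coverage_pct = cov, stringsAsFactors = FALSE)
}

test_that("hit filtering is inclusive at every cutoff boundary", {
  hits <- rbind(
    hit_row("q1", "t1", 1e-6, 120, 35),   # passes the final cutoffs
    hit_row("q2", "t1", 1e-6, 120, 25),   # fails identity
    hit_row("q3", "t1", 1e-5, 100, 30),   # exactly at every boundary
    hit_row("q4", "t1", 1e-4, 120, 35),   # fails e-value
    hit_row("q5", "t1", 1e-6, 99, 35))    # fails length
  kept <- filter_hits(hits, max_e_value = 1e-5, min_length = 100,
                      min_identity_pct = 30)
  expect_setequal(kept$query, c("q1", "q3"))
})

test_that("query-coverage mode supports the curation-stage criteria", {
  hits <- rbind(hit_row("q1", "t1", 1e-12, 40, 45, cov = 85),
                hit_row("q2", "t1", 1e-12, 400, 45, cov = 60))
  kept <- filter_hits(hits, max_e_value = 1e-10, min_length = 80,
                      min_identity_pct = 40,
                      length_criterion = "query_coverage")
  expect_identical(kept$query, "q1")
})

test_that("GPR transfer uses set semantics over retained hits", {
  template <- list(rxn1 = "tA and tB", rxn2 = "tZ")
  hits <- rbind(hit_row("qX", "tA", 1e-9, 150, 50),
                hit_row("qY", "tB", 1e-9, 150, 50),
                hit_row("qX", "tB", 1e-9, 150, 50))  # qX hits both
  draft <- transfer_gprs(hits, template)
  expect_setequal(draft$rxn1, c("qX", "qY"))
  # one target gene hitting two template genes is counted once
  expect_equal(sum(draft$rxn1 == "qX"), 1L)
  # no retained hits for rxn2: empty assignment, not NULL
  expect_identical(draft$rxn2, character(0))
})

test_that("draft scoring counts gene slots and unique genes separately", {
  ref <- list(r1 = c("g1", "g2"))
  draft <- list(r1 = c("g1", "g3"))
  sc <- score_draft(draft, ref)
  expect_equal(sc$tp_accumulative, 1)
  expect_equal(sc$fp_accumulative, 1)
  expect_equal(sc$fn_accumulative, 1)
  expect_equal(sc$unique_fp, 1)
  expect_equal(sc$unique_fn, 1)

  # one wrong gene recurring in 4 reactions: 4 slots, 1 unique gene
  ref4 <- list(r1 = "a1", r2 = "a2", r3 = "a3", r4 = "a4")
  draft4 <- lapply(ref4, function(g) c(g, "g3"))
  sc4 <- score_draft(draft4, ref4)
  expect_equal(sc4$fp_accumulative, 4)
  expect_equal(sc4$unique_fp, 1)
  expect_equal(sc4$fn_accumulative, 0)

  # a perfect draft
  perfect <- score_draft(ref4, ref4)
  expect_equal(perfect$fp_accumulative, 0)
  expect_equal(perfect$fn_accumulative, 0)
  expect_equal(perfect$tp_accumulative, 4)

  expect_warning(score_draft(c(draft, list(rX = "g9")), ref),
                 "absent from reference")
})

template_gprs <- list(r1 = "tA and tB", r2 = "tC", r3 = "tD or tE",
                      r4 = "tF")
reference <- list(r1 = c("q1", "q2"), r2 = "q3", r3 = c("q4", "q5"),
                  r4 = "q6")

test_that("the default grid spans 384 cutoff combinations", {
  hom <- gen_homology_table(3, template_gprs, reference, n_decoys = 30)
  tab <- grid_search(hom$hits, template_gprs, reference)
  expect_equal(nrow(tab), 384)
  # a 1x1x1 grid equals a single filter/transfer/score run
  g1 <- grid_search(hom$hits, template_gprs, reference,
                    grid = list(e_values = 1e-5, lengths = 100,
                                identities = 30))
  expect_equal(nrow(g1), 1)
  kept <- filter_hits(hom$hits, 1e-5, 100, 30)
  direct <- score_draft(transfer_gprs(kept, template_gprs), reference)
  expect_equal(g1$tp_accumulative, direct$tp_accumulative)
  expect_equal(g1$unique_fp, direct$unique_fp)
})

test_that("reference gene slots are conserved and cutoffs act monotonically", {
  hom <- gen_homology_table(5, template_gprs, reference,
                            n_decoys = 40, decoys_above = 5)
  tab <- grid_search(hom$hits, template_gprs, reference)
  total_slots <- sum(lengths(reference))
  expect_true(all(tab$tp_accumulative + tab$fn_accumulative ==
                    total_slots))
  expect_true(all(tab$tp_accumulative >= tab$unique_fp * 0))
  expect_true(all(tab$fp_accumulative >= tab$unique_fp))
  expect_true(all(tab$fn_accumulative >= tab$unique_fn))

  # relaxing one cutoff at a time never loses TPs or FPs
  for (fix_len in unique(tab$min_length)[1:2]) {
    for (fix_id in unique(tab$min_identity_pct)[1:2]) {
      sl <- tab[tab$min_length == fix_len &
                  tab$min_identity_pct == fix_id, ]
      sl <- sl[order(sl$max_e_value), ]   # relaxing e-value
      expect_true(all(diff(sl$tp_accumulative) >= 0))
      expect_true(all(diff(sl$fp_accumulative) >= 0))
      expect_true(all(diff(sl$fn_accumulative) <= 0))
    }
  }
})

test_that("the grid row at the planting thresholds recovers the truth", {
  hom <- gen_homology_table(9, template_gprs, reference, n_decoys = 60)
  tab <- grid_search(hom$hits, template_gprs, reference,
                     grid = list(e_values = 1e-5, lengths = 100,
                                 identities = 30))
  expect_equal(tab$fn_accumulative, 0)
  expect_equal(tab$unique_fp, 0)
  expect_equal(tab$tp_accumulative, sum(lengths(reference)))

  # an all-decoy table yields zero true positives
  decoy_only <- hom$hits[grepl("^decoy", hom$hits$query), ]
  sc <- score_draft(
    transfer_gprs(filter_hits(decoy_only, 1e-5, 100, 30),
                  template_gprs), reference)
  expect_equal(sc$tp_accumulative, 0)
})

test_that("decoys straddling a cutoff contribute exactly the planted FPs", {
  hom <- gen_homology_table(11, template_gprs, reference,
                            n_decoys = 30, decoys_above = 4)
  kept <- filter_hits(hom$hits, 1e-5, 100, 30)
  draft <- transfer_gprs(kept, template_gprs)
  sc <- score_draft(draft, reference)
  expect_equal(sc$unique_fp, length(hom$decoys_above_threshold))
  expect_gte(sc$fp_accumulative, sc$unique_fp)
})

test_that("hit tables round-trip through the outfmt-6 TSV reader", {
  hom <- gen_homology_table(2, template_gprs, reference, n_decoys = 10)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(qseqid = hom$hits$query, sseqid = hom$hits$subject,
               pident = hom$hits$identity_pct,
               length = hom$hits$alignment_length,
               evalue = hom$hits$e_value,
               qcovs = hom$hits$query_coverage_pct),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_hit_table(path)
  expect_equal(back$query, hom$hits$query)
  expect_equal(back$e_value, hom$hits$e_value, tolerance = 1e-12)
})
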