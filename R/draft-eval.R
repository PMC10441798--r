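#' Homology-transfer draft evaluation
#'
#' During semi-automatic reconstruction, GPR rules are transferred from
#' template organisms by protein homology. The quality of a draft
#' depends on three BLAST cutoffs — maximal e-value, minimal alignment
#' length (or query coverage) and minimal percent identity. These
#' functions rebuild that study: filter a hit table under a cutoff
#' triple, transfer template GPRs to target genes, score the draft
#' against a manually curated reference, and sweep a full cutoff grid.
#'
#' @name draft_eval
NULL

#' Read a BLAST outfmt-6 style hit table
#'
#' Expected tab-separated columns: `qseqid` (target-organism query
#' gene), `sseqid` (template subject gene), `pident`, `length`,
#' `evalue`, and optionally `qcovs`. A header line is detected and
#' skipped.
#'
#' @param path TSV file path.
#' @return data.frame of homology hits with columns `query`, `subject`,
#'   `identity_pct`, `alignment_length`, `e_value`,
#'   `query_coverage_pct` (NA when absent).
#' @export
read_hit_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("qseqid|query", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:5] <- c("qseqid", "sseqid", "pident", "length", "evalue")
    if (ncol(df) >= 6) names(df)[6] <- "qcovs"
  }
  data.frame(query = df$qseqid,
             subject = df$sseqid,
             identity_pct = as.numeric(df$pident),
             alignment_length = as.integer(df$length),
             e_value = as.numeric(df$evalue),
             query_coverage_pct = if ("qcovs" %in% names(df)) {
               as.numeric(df$qcovs)
             } else NA_real_,
             stringsAsFactors = FALSE)
}

#' Filter homology hits under a cutoff triple
#'
#' A hit is retained iff `e_value <= max_e_value` AND the length
#' criterion `>= min_length` AND `identity_pct >= min_identity_pct`
#' (all comparisons inclusive at the boundary).
#'
#' @param hits data.frame as returned by [read_hit_table()].
#' @param max_e_value maximal e-value.
#' @param min_length minimal alignment length in amino acids (or
#'   minimal query coverage in percent when
#'   `length_criterion = "query_coverage"`).
#' @param min_identity_pct minimal percent identity.
#' @param length_criterion `"alignment_length"` (default) or
#'   `"query_coverage"` — manual curation stages typically switch to a
#'   coverage cutoff (e.g. e-value <= 1e-10, coverage >= 80%).
#' @return the retained subset of `hits`.
#' @export
filter_hits <- function(hits, max_e_value, min_length, min_identity_pct,
                        length_criterion = c("alignment_length",
                                             "query_coverage")) {
  length_criterion <- match.arg(length_criterion)
  len <- if (length_criterion == "alignment_length") {
    hits$alignment_length
  } else {
    hits$query_coverage_pct
  }
  keep <- hits$e_value <= max_e_value &
    len >= min_length &
    hits$identity_pct >= min_identity_pct
  hits[keep & !is.na(keep), , drop = FALSE]
}

#' Transfer template GPRs to target genes through retained hits
#'
#' For each reaction, the draft assignment is the set of target-organism
#' genes having at least one retained hit to any gene of the reaction's
#' template GPR. A target gene hitting several template genes of the
#' same reaction is counted once (set semantics). Reactions with no
#' retained hit get an empty assignment (a missing reaction).
#'
#' @param hits retained hits (see [filter_hits()]).
#' @param template_gprs named list, reaction id -> GPR rule string over
#'   template gene ids (or a character vector of rules).
#' @return named list, reaction id -> character vector of target gene
#'   ids (possibly empty).
#' @export
transfer_gprs <- function(hits, template_gprs) {
  hits_by_subject <- split(hits$query, hits$subject)
  out <- lapply(template_gprs, function(rule) {
    tg <- gpr_genes(parse_gpr(rule))
    sort(unique(unlist(hits_by_subject[tg], use.names = FALSE)))
  })
  lapply(out, function(x) if (is.null(x)) character(0) else x)
}

#' Score a draft GPR assignment against a curated reference
#'
#' Per reference reaction r: true positives are `|draft(r)
#' intersect ref(r)|`, false positives `|draft(r) \ ref(r)|`, false
#' negatives `|ref(r) \ draft(r)|`, each accumulated over reactions
#' (gene slots, so one wrong gene assigned in four reactions counts
#' four times). `unique_fp`/`unique_fn` count the distinct genes behind
#' those slots. Draft reactions absent from the reference are ignored
#' with a warning.
#'
#' @param draft named list, reaction id -> target gene set.
#' @param reference named list, reaction id -> curated true gene set
#'   (non-empty).
#' @return one-row data.frame with `tp_accumulative`,
#'   `fp_accumulative`, `fn_accumulative`, `unique_fp`, `unique_fn`.
#' @export
score_draft <- function(draft, reference) {
  extra <- setdiff(names(draft), names(reference))
  if (length(extra) > 0) {
    warning("draft reactions absent from reference ignored: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  fp_genes <- character(0); fn_genes <- character(0)
  for (r in names(reference)) {
    ref_g <- reference[[r]]
    d_g <- draft[[r]]
    if (is.null(d_g)) d_g <- character(0)
    tp <- tp + length(intersect(d_g, ref_g))
    wrong <- setdiff(d_g, ref_g)
    miss <- setdiff(ref_g, d_g)
    fp <- fp + length(wrong)
    fn <- fn + length(miss)
    fp_genes <- c(fp_genes, wrong)
    fn_genes <- c(fn_genes, miss)
  }
  data.frame(tp_accumulative = tp, fp_accumulative = fp,
             fn_accumulative = fn,
             unique_fp = length(unique(fp_genes)),
             unique_fn = length(unique(fn_genes)))
}

#' Default cutoff grid: 8 e-values x 6 lengths x 8 identities = 384
#' draft parameterisations spanning e-value 1e-30..1e-5, alignment
#' length 50..150 aa and identity 20..40%.
#' @export
default_cutoff_grid <- function() {
  list(e_values = c(1e-30, 1e-25, 1e-20, 1e-15, 1e-10, 1e-8, 1e-6, 1e-5),
       lengths = c(50, 70, 90, 110, 130, 150),
       identities = c(20, 23, 26, 29, 32, 35, 38, 40))
}

#' Evaluate the full cutoff grid
#'
#' Runs filter -> transfer -> score over the Cartesian product of the
#' cutoff lists and returns one row per grid point, sorted by
#' (e-value, length, identity).
#'
#' @param hits homology hit table ([read_hit_table()]).
#' @param template_gprs named GPR rules over template genes.
#' @param reference curated reference (named list of gene sets).
#' @param grid list with `e_values`, `lengths`, `identities`; defaults
#'   to [default_cutoff_grid()].
#' @param length_criterion see [filter_hits()].
#' @return data.frame with the cutoffs (`max_e_value`, `min_length`,
#'   `min_identity_pct`) and the five quality metrics per row.
#' @export
grid_search <- function(hits, template_gprs, reference,
                        grid = default_cutoff_grid(),
                        length_criterion = "alignment_length") {
  stopifnot(length(grid$e_values) > 0, length(grid$lengths) > 0,
            length(grid$identities) > 0)
  pts <- expand.grid(min_identity_pct = sort(grid$identities),
                     min_length = sort(grid$lengths),
                     max_e_value = sort(grid$e_values))
  pts <- pts[order(pts$max_e_value, pts$min_length,
                   pts$min_identity_pct), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    kept <- filter_hits(hits, pts$max_e_value[i], pts$min_length[i],
                        pts$min_identity_pct[i],
                        length_criterion = length_criterion)
    draft <- transfer_gprs(kept, template_gprs)
    cbind(pts[i, c("max_e_value", "min_length", "min_identity_pct"),
              drop = FALSE],
          suppressWarnings(score_draft(draft, reference)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
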