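#' Phenotype-microarray (Biolog-style) validation
#'
#' Experimental growth on single-substrate plates is binarized, each
#' mapped substrate is simulated by FBA with every alternative source
#' of the tested nutrient class closed, and predictions are compared to
#' experiment through the full confusion-matrix statistic panel
#' including the Matthews correlation coefficient (MCC).
#'
#' @name phenotype_validation
NULL

#' Binarize an OD600 time series into a growth call
#'
#' Growth is called when the maximal OD within the horizon exceeds the
#' initial OD by strictly more than `threshold` (an increase of exactly
#' the threshold is no growth).
#'
#' @param od numeric OD600 readings.
#' @param time_h observation times in hours (same length as `od`).
#' @param threshold minimal OD600 increase (default 0.02).
#' @param horizon_h evaluation horizon in hours (default 96).
#' @return `"growth"` or `"no_growth"`.
#' @export
binarize_growth <- function(od, time_h, threshold = 0.02,
                            horizon_h = 96) {
  if (length(od) < 2 || length(time_h) != length(od)) {
    stop("need >= 2 aligned time points", call. = FALSE)
  }
  if (horizon_h > max(time_h) + 1e-9) {
    stop("horizon exceeds the series span", call. = FALSE)
  }
  inside <- time_h <= horizon_h + 1e-9
  if (max(od[inside]) - od[which.min(time_h)] > threshold) {
    "growth"
  } else "no_growth"
}

#' Simulate growth on each plate substrate
#'
#' For each mapped plate record: start from the base medium, close the
#' uptake of every exchange listed as an alternative source of the
#' tested nutrient class, open the substrate's exchange, and run FBA.
#' Predicted growth means the optimal growth rate exceeds
#' [GROWTH_THRESHOLD]. Each well is simulated on a fresh copy of the
#' medium, so wells are order-independent. Records flagged unmapped are
#' skipped (they are excluded from the confusion matrix, mirroring the
#' exclusion of compounds without defined pathways); mapped records
#' whose exchange is absent from the model are skipped with a warning.
#'
#' Chemoheterotrophic plate conditions close photon and CO2 uptake
#' (and N2 for aerobic runs) through `closed_exchanges`. For nitrogen
#' plates the base medium must keep a carbon source (e.g. sucrose)
#' open; for carbon plates it supplies the nitrogen source (ammonium),
#' minerals and O2.
#'
#' @param model a [metabolic_model()].
#' @param plate data.frame with columns `substrate`, `exchange` (id or
#'   `"-"`/`NA` for unmapped) and `call` (`"growth"`/`"no_growth"`).
#' @param base_medium named uptake vector (see [fba()]) supplying
#'   everything but the tested class.
#' @param class_exchanges exchange ids that are sources of the tested
#'   nutrient class (carbon or nitrogen); all of them are closed before
#'   the tested substrate is opened.
#' @param uptake uptake bound granted to the tested substrate
#'   (default 10 mmol/gDW/h).
#' @param closed_exchanges exchange ids force-closed in every
#'   simulation (photons, CO2, N2 as the condition requires).
#' @return data.frame with one row per compared substrate: `substrate`,
#'   `exchange`, `experimental`, `predicted`, `mu`.
#' @export
simulate_plate <- function(model, plate, base_medium, class_exchanges,
                           uptake = 10, closed_exchanges = character(0)) {
  rows <- list()
  for (i in seq_len(nrow(plate))) {
    ex <- plate$exchange[i]
    if (is.na(ex) || ex %in% c("-", "")) next
    if (!ex %in% names(model$reactions)) {
      warning("plate substrate ", plate$substrate[i],
              ": exchange ", ex, " not in model; record skipped")
      next
    }
    med <- base_medium
    med <- med[!names(med) %in% c(class_exchanges, closed_exchanges)]
    med[ex] <- uptake
    sol <- fba(model, medium = med)
    mu <- if (sol$status == "optimal") sol$objective else 0
    rows[[length(rows) + 1]] <- data.frame(
      substrate = plate$substrate[i], exchange = ex,
      experimental = plate$call[i],
      predicted = if (mu > GROWTH_THRESHOLD) "growth" else "no_growth",
      mu = mu, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(substrate = character(0), exchange = character(0),
                      experimental = character(0),
                      predicted = character(0), mu = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build a confusion matrix from experimental and predicted calls
#'
#' @param experimental,predicted character vectors of
#'   `"growth"`/`"no_growth"` calls (experiment defines the truth).
#' @return list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(experimental, predicted) {
  stopifnot(length(experimental) == length(predicted))
  e <- experimental == "growth"
  p <- predicted == "growth"
  list(tp = sum(e & p), tn = sum(!e & !p),
       fp = sum(!e & p), fn = sum(e & !p))
}

#' Confusion-matrix statistic panel
#'
#' Standard definitions: accuracy (tp+tn)/total, sensitivity
#' tp/(tp+fn), specificity tn/(tn+fp), positive predictive value
#' tp/(tp+fp), negative predictive value tn/(tn+fn), and
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)).
#' Any 0/0 ratio (including an MCC with a zero denominator factor) is
#' defined as 0 and listed in `undefined`. Reported values are rounded
#' half-up to two decimals, matching the conventional presentation;
#' raw values are retained.
#'
#' @param tp,tn,fp,fn non-negative counts, or a list with those fields
#'   as first argument.
#' @return a `validation_stats` list with `counts`, `raw` (exact
#'   values), `rounded` (2 decimals, half-up) and `undefined`
#'   (character vector of flagged 0/0 statistics).
#' @examples
#' confusion_stats(55, 12, 1, 11)$rounded
#' @export
confusion_stats <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    cm <- tp; tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  # double precision: the MCC denominator overflows 32-bit integers
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  undefined <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      0
    } else num / den
  }
  mcc_den_sq <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  raw <- c(
    accuracy = (tp + tn) / total,
    sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    specificity = safe_div(tn, tn + fp, "specificity"),
    positive_predicted = safe_div(tp, tp + fp, "positive_predicted"),
    negative_predicted = safe_div(tn, tn + fn, "negative_predicted"),
    mcc = if (mcc_den_sq == 0) {
      undefined <- c(undefined, "mcc")
      0
    } else (tp * tn - fp * fn) / sqrt(mcc_den_sq))
  structure(list(counts = counts, raw = raw,
                 rounded = round_half_up(raw, 2),
                 undefined = undefined),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat("<validation_stats> tp/tn/fp/fn:",
      paste(x$counts, collapse = "/"), "\n")
  print(x$rounded)
  invisible(x)
}

#' Round half away from zero
#'
#' Unlike [round()] (banker's rounding), 0.625 at 2 digits gives 0.63.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Growth-rate prediction accuracy (percent)
#'
#' Relative-error accuracy: `100 * (1 - |predicted - experimental| /
#' experimental)`, floored at zero and rounded half-up to the nearest
#' integer for reporting.
#'
#' @param experimental,predicted growth rates in 1/h (experimental
#'   must be positive).
#' @return integer percent accuracy (vectorised).
#' @examples
#' rate_accuracy(0.0075, 0.0088)  # 83
#' @export
rate_accuracy <- function(experimental, predicted) {
  if (any(experimental <= 0)) {
    stop("experimental growth rate must be positive", call. = FALSE)
  }
  acc <- 100 * (1 - abs(predicted - experimental) / experimental)
  as.integer(round_half_up(pmax(acc, 0)))
}
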