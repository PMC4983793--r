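#' IP efficiency index from immunoblot band intensities
#'
#' The "% tot. lysate" index: both bands are first scaled to
#' whole-reaction equivalents by dividing by the fraction loaded on the
#' gel, then the IP band is expressed as a percentage of the input band:
#' `100 * (ip / ipFractionLoaded) / (input / inputFractionOfLysate)`.
#' Rescaling both band intensities by a common factor (gel exposure)
#' leaves the index unchanged. Values above 100% are possible with noisy
#' densitometry and are flagged with a warning rather than rejected.
#'
#' @param ipBand IP-lane band intensity (>= 0).
#' @param inputBand Total-lysate (input) lane band intensity (> 0).
#' @param ipFractionLoaded Fraction of the IP reaction loaded on the gel,
#'   in (0, 1].
#' @param inputFractionOfLysate Fraction of the lysate represented by the
#'   input lane, in (0, 1].
#' @return Numeric percentage (vectorised).
#' @examples
#' percentTotalLysate(50, 100, 0.5, 0.05)   # 5
#' @export
percentTotalLysate <- function(ipBand, inputBand, ipFractionLoaded,
                               inputFractionOfLysate) {
  stopifnot(all(ipBand >= 0), all(ipFractionLoaded > 0),
            all(ipFractionLoaded <= 1), all(inputFractionOfLysate > 0),
            all(inputFractionOfLysate <= 1))
  if (any(inputBand <= 0)) {
    stop("undefined index: input band intensity must be > 0")
  }
  pct <- 100 * (ipBand / ipFractionLoaded) /
    (inputBand / inputFractionOfLysate)
  if (any(pct > 100)) {
    warning("% tot. lysate above 100% for ", sum(pct > 100),
            " measurement(s); likely densitometry noise")
  }
  pct
}

#' Classify antibodies from their FLIP signals
#'
#' Adds the screening calls to a table of per-antibody results. The
#' reported FLIP value clips negatives to zero (a display convention: a
#' background IP brighter than the test IP is reported as zero); the FLIP
#' call is positive iff the signed signal is greater than zero. Signal
#' tiers annotate the separation seen between true and false positives:
#' `high` above 1.0 (where true positives concentrate), `low` below 0.6
#' (where all false positives fell), `intermediate` between. When an
#' IP/immunoblot call is available the record is labelled `concordant`,
#' `flip_false_positive` (FLIP positive, blot negative) or
#' `flip_false_negative`.
#'
#' @param records data.frame with at least `flipSignal`; optional
#'   `ipibCall` ("positive"/"negative"/NA).
#' @param highTier,lowTier Tier thresholds (defaults 1.0 and 0.6).
#' @return The input with `flipReported`, `flipCall`, `tier` and (when
#'   `ipibCall` exists) `concordanceClass` columns added.
#' @export
classifyScreen <- function(records, highTier = 1.0, lowTier = 0.6) {
  stopifnot(is.data.frame(records), "flipSignal" %in% names(records))
  s <- records$flipSignal
  records$flipReported <- pmax(s, 0)
  records$flipCall <- ifelse(s > 0, "positive", "negative")
  records$tier <- ifelse(s > highTier, "high",
                         ifelse(s < lowTier, "low", "intermediate"))
  if ("ipibCall" %in% names(records)) {
    fc <- records$flipCall == "positive"
    ic <- records$ipibCall == "positive"
    records$concordanceClass <- ifelse(is.na(records$ipibCall), NA_character_,
      ifelse(fc == ic, "concordant",
             ifelse(fc, "flip_false_positive", "flip_false_negative")))
  }
  records
}

#' FLIP vs IP/immunoblot concordance
#'
#' Confusion summary of the two assays over a screened antibody panel,
#' treating the IP/immunoblot call as the reference: TP (both positive),
#' TN (both negative), FP (FLIP positive only), FN (FLIP negative only),
#' and the concordance rate `(TP + TN) / total`.
#'
#' @param records data.frame with `flipCall` and `ipibCall` columns, both
#'   "positive"/"negative" (e.g. from [classifyScreen()]).
#' @return List: `TP`, `TN`, `FP`, `FN`, `n`, `rate`, and `fractions`
#'   (per-class proportions).
#' @examples
#' # the published 46-antibody panel realises TP=28 FN=6 FP=3 TN=9
#' calls <- data.frame(
#'   flipCall = rep(c("positive", "negative", "positive", "negative"),
#'                  c(28, 6, 3, 9)),
#'   ipibCall = rep(c("positive", "positive", "negative", "negative"),
#'                  c(28, 6, 3, 9)))
#' concordanceSummary(calls)$rate   # 37/46 ~ 0.804
#' @export
concordanceSummary <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("flipCall", "ipibCall") %in% names(records)))
  if (nrow(records) == 0) stop("empty record set")
  if (anyNA(records$flipCall) || anyNA(records$ipibCall)) {
    stop("every record needs both a FLIP and an IP/IB call")
  }
  f <- records$flipCall == "positive"
  b <- records$ipibCall == "positive"
  tp <- sum(f & b); tn <- sum(!f & !b); fp <- sum(f & !b); fn <- sum(!f & b)
  n <- nrow(records)
  list(TP = tp, TN = tn, FP = fp, FN = fn, n = n, rate = (tp + tn) / n,
       fractions = c(TP = tp, TN = tn, FP = fp, FN = fn) / n)
}

#' Correlation of FLIP signal with IP efficiency
#'
#' Squared Pearson correlation between the FLIP signal and the % tot.
#' lysate index across a screened panel; the R^2 of the best-fit line
#' relating the two assays. Records with either value missing are dropped
#' and counted.
#'
#' @param records data.frame with `flipSignal` and `percentTotalLysate`
#'   columns.
#' @return List: `rSquared`, `nUsed`, `nDropped`.
#' @export
screenCorrelation <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("flipSignal", "percentTotalLysate") %in% names(records)))
  ok <- stats::complete.cases(records[, c("flipSignal", "percentTotalLysate")])
  x <- records$flipSignal[ok]
  y <- records$percentTotalLysate[ok]
  if (length(x) < 3) stop("need >= 3 complete records to correlate")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance in one of the variables")
  }
  list(rSquared = stats::cor(x, y)^2, nUsed = length(x),
       nDropped = sum(!ok))
}

#' Read and write screening tables
#'
#' `readScreenTable()` reads a CSV with one row per antibody
#' (`antibodyId`, `target`, `flipSignal`, and optionally the blot columns
#' `ipBand`, `inputBand`, `ipFractionLoaded`, `inputFractionOfLysate`,
#' `ipibCall`); when the four blot columns are present the
#' `percentTotalLysate` index is computed on load. `writeScreenReport()`
#' writes a classified table plus a JSON concordance summary.
#'
#' @param path Input CSV path.
#' @return For `readScreenTable()`, a data.frame.
#' @export
readScreenTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("antibodyId", "flipSignal") %in% names(df)))
  blot <- c("ipBand", "inputBand", "ipFractionLoaded", "inputFractionOfLysate")
  if (all(blot %in% names(df))) {
    df$percentTotalLysate <- percentTotalLysate(
      df$ipBand, df$inputBand, df$ipFractionLoaded, df$inputFractionOfLysate)
  }
  df
}

#' @rdname readScreenTable
#' @param records Classified data.frame (see [classifyScreen()]).
#' @param dir Output directory.
#' @param basename File stem for `<stem>.csv` / `<stem>_concordance.json`.
#' @export
writeScreenReport <- function(records, dir, basename = "screen") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(basename, ".csv"))
  utils::write.csv(records, csv, row.names = FALSE)
  out <- csv
  if (all(c("flipCall", "ipibCall") %in% names(records)) &&
      !anyNA(records$ipibCall)) {
    js <- file.path(dir, paste0(basename, "_concordance.json"))
    jsonlite::write_json(concordanceSummary(records), js, auto_unbox = TRUE,
                         digits = NA)
    out <- c(out, js)
  }
  invisible(out)
}
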