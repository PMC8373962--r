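# Biogeochemical screening diagnostics: the theoretical nitrification
# d18O window, denitrification/mixing correlation tests, and
# water-quality exceedance flags.

#' Theoretical nitrification d18O-NO3 window
#'
#' During nitrification roughly one third of the nitrate oxygen derives
#' from dissolved O2 and two thirds from ambient water, so nitrate
#' produced in situ should fall in
#' `(1/3) d18O_O2 + (2/3) d18O_H2O` for the local range of water d18O.
#'
#' @param d18O_H2O_min,d18O_H2O_max Range of ambient-water d18O (per
#'   mil vs VSMOW), min <= max.
#' @param d18O_O2 d18O of dissolved oxygen (per mil; default +23.5).
#' @return A list of class `"nitrification_window"` with `lo`, `hi`,
#'   `d18O_O2`, `d18O_H2O_range`.
#' @export
nitrification_o18_range <- function(d18O_H2O_min, d18O_H2O_max,
                                    d18O_O2 = 23.5) {
  if (d18O_H2O_min > d18O_H2O_max) stop("d18O_H2O_min must be <= d18O_H2O_max")
  lo <- d18O_O2 / 3 + 2 * d18O_H2O_min / 3
  hi <- d18O_O2 / 3 + 2 * d18O_H2O_max / 3
  structure(list(lo = lo, hi = hi, d18O_O2 = d18O_O2,
                 d18O_H2O_range = c(d18O_H2O_min, d18O_H2O_max)),
            class = "nitrification_window")
}

#' @export
print.nitrification_window <- function(x, ...) {
  cat(sprintf(
    "Nitrification d18O-NO3 window: [%+.2f, %+.2f] permil\n  (d18O-O2 = %+.1f, d18O-H2O in [%+.1f, %+.1f])\n",
    x$lo, x$hi, x$d18O_O2, x$d18O_H2O_range[1], x$d18O_H2O_range[2]))
  invisible(x)
}

#' Classify samples against the nitrification window
#'
#' Compares each sample's d18O-NO3 to the closed interval `[lo, hi]`:
#' values on either bound count as `within`.
#'
#' @param samples Canonical sample data.frame.
#' @param window A [nitrification_o18_range()] window.
#' @return Character vector per sample: `"within"`, `"above"`,
#'   `"below"`, or `"not_evaluable"` when d18O-NO3 is missing.
#' @export
classify_nitrification <- function(samples, window) {
  stopifnot(inherits(window, "nitrification_window"))
  v <- samples$d18O_NO3
  out <- rep("not_evaluable", length(v))
  ok <- is.finite(v)
  out[ok & v < window$lo] <- "below"
  out[ok & v > window$hi] <- "above"
  out[ok & v >= window$lo & v <= window$hi] <- "within"
  out
}

#' Pearson correlation with a two-tailed p-value
#'
#' Pairs with any missing value are dropped; the p-value comes from the
#' t distribution with n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors.
#' @return A list `(r, p, n)`; `r` and `p` are NA (not evaluable) when
#'   fewer than 3 complete pairs remain or either variable has zero
#'   variance.
#' @export
pearson_with_p <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Denitrification / mixing correlation screen for one set of samples
#'
#' Computes the three tracer relationships used to attribute nitrogen
#' transformation processes: (a) d15N-NO3 versus ln(NO3), (b) d18O-NO3
#' versus d15N-NO3, and (c) conductivity versus NO3.  The default
#' interpretation rule codifies the standard narrative: a significant
#' negative (a) or significant positive (b) indicates residual-pool
#' heavy-isotope enrichment (Rayleigh-type denitrification); a
#' significant negative (b) indicates mixing without enrichment; all
#' else is not significant.  The rule operates per pair and is
#' overridable through `alpha`.
#'
#' Samples with NO3 <= 0 are dropped pairwise from (a) with a notice
#' (their logarithm is undefined).
#'
#' @param samples Canonical sample data.frame (one region or cluster
#'   group).
#' @param alpha Two-tailed significance level (default 0.01; 0.05 is
#'   the common alternative).
#' @param scope Label recorded in the output.
#' @return A data.frame with one row per pair: `scope`, `pair`, `r`,
#'   `p`, `n`, `interpretation` (one of `denitrification_signal`,
#'   `mixing_or_none`, `not_significant`, `not_evaluable`).
#' @export
denitrification_assessment <- function(samples, alpha = 0.01, scope = "all") {
  no3 <- samples$no3
  bad <- is.finite(no3) & no3 <= 0
  if (any(bad)) {
    message("dropping ", sum(bad),
            " sample(s) with NO3 <= 0 from the ln(NO3) correlation")
    no3[bad] <- NA_real_
  }
  a <- pearson_with_p(samples$d15N_NO3, log(no3))
  b <- pearson_with_p(samples$d18O_NO3, samples$d15N_NO3)
  cc <- pearson_with_p(samples$cond, samples$no3)
  interp <- function(res, rule) {
    if (is.na(res$r)) return("not_evaluable")
    sig <- !is.na(res$p) && res$p < alpha
    if (!sig) return("not_significant")
    rule(res$r)
  }
  rows <- list(
    data.frame(scope = scope, pair = "d15N_vs_lnNO3", r = a$r, p = a$p, n = a$n,
               interpretation = interp(a, function(r) {
                 if (r < 0) "denitrification_signal" else "not_significant"
               }), stringsAsFactors = FALSE),
    data.frame(scope = scope, pair = "d18O_vs_d15N", r = b$r, p = b$p, n = b$n,
               interpretation = interp(b, function(r) {
                 if (r > 0) "denitrification_signal" else "mixing_or_none"
               }), stringsAsFactors = FALSE),
    data.frame(scope = scope, pair = "cond_vs_no3", r = cc$r, p = cc$p, n = cc$n,
               interpretation = interp(cc, function(r) {
                 if (r > 0) "denitrification_signal" else "not_significant"
               }), stringsAsFactors = FALSE)
  )
  out <- do.call(rbind, rows)
  # conductivity-nitrate correlation marks sewage/manure influence, not
  # denitrification; relabel its positive-significant outcome
  out$interpretation[out$pair == "cond_vs_no3" &
                       out$interpretation == "denitrification_signal"] <-
    "pollution_input_signal"
  out
}

#' Water-quality exceedance flags
#'
#' Flags each sample against the drinking-water nitrate guideline
#' (default 50 mg/L) and a configurable total-nitrogen class threshold.
#' Comparisons are strict (`>`); a missing concentration yields a
#' not-evaluable flag (NA), never FALSE.
#'
#' @param samples Canonical sample data.frame.
#' @param who_no3 Nitrate threshold in mg/L.
#' @param class_v_tn Total-nitrogen threshold in mg/L.
#' @return A data.frame per sample: `sample_id`, `who_no3_exceeded`,
#'   `class_v_tn_exceeded` (logical, NA = not evaluable), and the
#'   thresholds used.
#' @export
exceedance_flags <- function(samples, who_no3 = 50, class_v_tn = 2.0) {
  stopifnot(who_no3 > 0, class_v_tn > 0)
  data.frame(
    sample_id = samples$sample_id,
    who_no3_exceeded = ifelse(is.finite(samples$no3), samples$no3 > who_no3, NA),
    class_v_tn_exceeded = ifelse(is.finite(samples$tn), samples$tn > class_v_tn, NA),
    who_no3_threshold = who_no3,
    class_v_tn_threshold = class_v_tn,
    stringsAsFactors = FALSE
  )
}
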