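#' Box-plot outlier fences (Tukey)
#'
#' Quartiles by linear interpolation (`stats::quantile` type 7, the R
#' default used for the published box plots). Values below
#' `Q1 - c * IQR` are outliers: mild at `c = 1.5`, extreme at `c = 3`.
#'
#' @param x Numeric values.
#' @param mild,extreme Fence coefficients.
#' @return Object of class `outlier_fences` with `q1`, `q3`, `iqr` and the
#'   lower `mild_fence` / `extreme_fence`.
#' @export
outlier_fences <- function(x, mild = 1.5, extreme = 3.0) {
  stopifnot(mild > 0, extreme > 0)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 mild = mild, extreme = extreme,
                 mild_fence = q[1] - mild * iqr,
                 extreme_fence = q[1] - extreme * iqr),
            class = "outlier_fences")
}

#' Scan element-pair divergence times for horizontal-transfer signatures
#'
#' Vertically inherited element lineages diverge when their hosts do, so an
#' element pair whose divergence time falls far below the distribution of
#' its peers — or far below the host-pair divergence itself — is a
#' horizontal-transfer (HT) candidate. Two complementary triggers are
#' recorded: the Tukey lower-fence outlier class of the element divergence
#' time within the supplied distribution (mild `1.5 x IQR`, extreme
#' `3 x IQR`), and a ratio rule flagging pairs with element divergence below
#' `ratio_threshold` times the host divergence. With fewer than `min_pairs`
#' rows the fences are skipped (ratio rule only) with a warning.
#'
#' @param pair_divergences Data frame with columns `pair` (label),
#'   `host_a`, `host_b`, `t_ma` (element-pair divergence, Ma) and
#'   optionally `se_ma`.
#' @param host_tbl A [host_table()] covering every host pair.
#' @param mild,extreme Fence coefficients.
#' @param ratio_threshold Element/host divergence ratio below which the
#'   ratio trigger fires.
#' @param min_pairs Minimum rows for meaningful fences.
#' @return Data frame of class `ht_candidates`: one row per input pair with
#'   `host_divergence_ma`, `ratio`, `outlier_class`
#'   (`none`/`mild`/`extreme`), `ratio_flag`, and `is_candidate`; the
#'   fences are attached as attribute `fences`.
#' @export
ht_scan <- function(pair_divergences, host_tbl, mild = 1.5, extreme = 3.0,
                    ratio_threshold = 0.5, min_pairs = 5L) {
  need <- c("pair", "host_a", "host_b", "t_ma")
  stopifnot(all(need %in% names(pair_divergences)))
  pd <- as.data.frame(pair_divergences)
  pd$host_divergence_ma <- mapply(function(a, b)
    host_divergence(host_tbl, a, b), pd$host_a, pd$host_b)
  pd$ratio <- pd$t_ma / pd$host_divergence_ma
  fences <- NULL
  if (nrow(pd) >= min_pairs) {
    fences <- outlier_fences(pd$t_ma, mild = mild, extreme = extreme)
    pd$outlier_class <- ifelse(pd$t_ma < fences$extreme_fence, "extreme",
                        ifelse(pd$t_ma < fences$mild_fence, "mild", "none"))
  } else {
    warning("fewer than ", min_pairs,
            " pairs: fence rule skipped, ratio rule only")
    pd$outlier_class <- "none"
  }
  pd$ratio_flag <- pd$ratio < ratio_threshold
  pd$is_candidate <- pd$outlier_class != "none" | pd$ratio_flag
  attr(pd, "fences") <- fences
  class(pd) <- c("ht_candidates", "data.frame")
  pd
}

#' Classify selection regime from a codon distance
#'
#' `dN/dS < 1` indicates purifying selection; `dS = 0` leaves the ratio
#' undefined.
#'
#' @param codon_distance A [nei_gojobori()] result (or any object with
#'   `omega`).
#' @return `"purifying"`, `"neutral-or-positive"` or `"undefined"`.
#' @export
selection_check <- function(codon_distance) {
  om <- codon_distance$omega
  if (is.null(om) || is.na(om)) return("undefined")
  if (om < 1) "purifying" else "neutral-or-positive"
}

#' Write an HT candidate report
#'
#' One TSV row per candidate with the evidence fields, plus a short text
#' summary. Round-trips through [utils::read.delim()].
#'
#' @param candidates An [ht_scan()] result.
#' @param path Output TSV path.
#' @param elements Optional [age_table()] result used to append
#'   youngest/oldest insertion ages of the involved subfamilies.
#' @return Invisibly, the data frame written.
#' @export
ht_report <- function(candidates, path, elements = NULL) {
  stopifnot(inherits(candidates, "ht_candidates"))
  out <- as.data.frame(candidates)[candidates$is_candidate, , drop = FALSE]
  if (!is.null(elements)) {
    sm <- elements$summary
    idx <- match(out$pair, sm$subfamily)
    out$youngest_insertion_ma <- sm$min_ma[idx]
    out$oldest_insertion_ma <- sm$max_ma[idx]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fences <- attr(candidates, "fences")
  msg <- if (nrow(out) == 0L) "no candidates" else
    sprintf("%d HT candidate(s); extreme fence at %.2f Ma", nrow(out),
            if (is.null(fences)) NA_real_ else fences$extreme_fence)
  message("ht_report: ", msg)
  invisible(out)
}
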