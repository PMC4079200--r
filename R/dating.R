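new_age_estimate <- function(t_ma, se_ma, clock, rate_used, k_or_ks) {
  structure(list(t_ma = t_ma, se_ma = se_ma, clock = clock,
                 rate_used = rate_used, k_or_ks = k_or_ks),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("%s age: %.3f%s Ma (k = %.4f, r = %.3g /site/yr)\n",
              x$clock, x$t_ma,
              if (is.na(x$se_ma)) "" else sprintf(" +/- %.3f", x$se_ma),
              x$k_or_ks, x$rate_used))
  invisible(x)
}

#' Insertion age of an element from its LTR divergence
#'
#' At insertion the two LTRs of a retroelement are identical; both then
#' accumulate substitutions independently, so an element of age `t` shows a
#' Kimura 2-parameter LTR-LTR distance of `k = 2 r t`. The age is therefore
#' `t = k / (2 r)` with `r` the intergenic substitution rate (default
#' 3.3e-8 /site/yr). Unequal-length LTRs are first aligned globally with
#' free end gaps (terminal overhangs excluded from counting).
#'
#' @param element An [element_record()] (or a list with `ltr5_seq`,
#'   `ltr3_seq` character fields).
#' @param rates A [rate_config()].
#' @param boot_reps Bootstrap replicates for the K2P SE.
#' @param seed RNG seed.
#' @param min_sites Minimum compared LTR sites for a reliable age.
#' @return An `age_estimate` (clock `"insertion"`).
#' @export
insertion_age <- function(element, rates = rate_config(), boot_reps = 500L,
                          seed = NULL, min_sites = 50L) {
  if (inherits(element, "element_record")) {
    l <- ltr_seqs(element)
  } else {
    l <- c(element$ltr5_seq, element$ltr3_seq)
  }
  if (nchar(l[1]) != nchar(l[2])) {
    al <- Biostrings::pairwiseAlignment(l[1], l[2], type = "overlap",
                                        substitutionMatrix = ntmat(),
                                        gapOpening = 4, gapExtension = 1)
    l <- c(as.character(Biostrings::alignedPattern(al)),
           as.character(Biostrings::alignedSubject(al)))
  }
  cs <- count_substitutions(l[1], l[2])
  if (cs$n_sites < min_sites)
    stop("unreliable age: only ", cs$n_sites, " comparable LTR sites")
  est <- k2p_distance(cs, boot_reps = boot_reps, seed = seed)
  t_yr <- est$k / (2 * rates$r_intergenic)
  se <- if (is.na(est$se_k)) NA_real_
        else est$se_k / (2 * rates$r_intergenic) / 1e6
  new_age_estimate(t_yr / 1e6, se, "insertion", rates$r_intergenic, est$k)
}

#' Insertion age from a precomputed LTR-LTR distance
#'
#' Convenience form of the same clock, `t = k / (2 r)`, for a distance
#' obtained elsewhere (e.g. a published `k`).
#'
#' @param k Substitutions/site between the two LTRs.
#' @param se_k Standard error of `k` (`NA` for none).
#' @param rate Intergenic substitution rate /site/yr.
#' @return An `age_estimate`.
#' @export
#' @examples
#' insertion_age_from_k(0.116, 0.017)  # ~1.758 Ma
insertion_age_from_k <- function(k, se_k = NA_real_, rate = 3.3e-8) {
  stopifnot(k >= 0, rate > 0)
  new_age_estimate(k / (2 * rate) / 1e6,
                   if (is.na(se_k)) NA_real_ else se_k / (2 * rate) / 1e6,
                   "insertion", rate, k)
}

#' Divergence time from a synonymous distance
#'
#' `T = ks / (2 r)` with `r` the synonymous substitution rate (default
#' 6.5e-9 /synonymous site/yr); the SE scales identically.
#'
#' @param ks Synonymous substitutions per synonymous site.
#' @param se_ks Standard error of `ks` (`NA` for none).
#' @param rate Synonymous substitution rate /site/yr.
#' @return An `age_estimate` (clock `"divergence"`).
#' @export
#' @examples
#' divergence_age(0.4343, rate = 1.67e-8)  # ~13 Ma
divergence_age <- function(ks, se_ks = NA_real_, rate = 6.5e-9) {
  stopifnot(ks >= 0, rate > 0)
  new_age_estimate(ks / (2 * rate) / 1e6,
                   if (is.na(se_ks)) NA_real_ else se_ks / (2 * rate) / 1e6,
                   "divergence", rate, ks)
}

#' Fold difference between two substitution rates
#'
#' @param rate_a,rate_b Rates (> 0).
#' @return List with `raw` ratio and nearest-integer `fold`.
#' @export
#' @examples
#' rate_fold_difference(3.3e-8, 6.5e-9)  # raw 5.08, fold 5
rate_fold_difference <- function(rate_a, rate_b) {
  stopifnot(rate_a > 0, rate_b > 0)
  raw <- rate_a / rate_b
  list(raw = raw, fold = as.integer(round(raw)))
}

#' Per-element insertion-age table with subfamily summaries
#'
#' One row per element plus, per subfamily label (empty labels grouped as
#' `"unassigned"`), summary rows with copy number and min/mean/max age.
#'
#' @param elements List of [element_record()]s.
#' @param rates A [rate_config()].
#' @param boot_reps,seed Passed to [insertion_age()].
#' @return List with data frames `elements` and `summary`.
#' @export
age_table <- function(elements, rates = rate_config(), boot_reps = 200L,
                      seed = NULL) {
  stopifnot(length(elements) >= 1L)
  rows <- lapply(seq_along(elements), function(i) {
    el <- elements[[i]]
    sub <- if (nzchar(el$subfamily %||% "")) el$subfamily else "unassigned"
    a <- tryCatch(
      insertion_age(el, rates, boot_reps = boot_reps,
                    seed = if (is.null(seed)) NULL else seed + i),
      error = function(e) e)
    if (inherits(a, "error")) {
      warning("element ", el$id, " not datable: ", conditionMessage(a))
      return(data.frame(id = el$id, host = el$host, subfamily = sub,
                        k = NA_real_, t_ma = NA_real_, se_ma = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(id = el$id, host = el$host, subfamily = sub,
               k = a$k_or_ks, t_ma = a$t_ma, se_ma = a$se_ma,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(per, per$subfamily), function(g)
    data.frame(subfamily = g$subfamily[1], n_copies = nrow(g),
               n_dated = sum(!is.na(g$t_ma)),
               min_ma = suppressWarnings(min(g$t_ma, na.rm = TRUE)),
               mean_ma = mean(g$t_ma, na.rm = TRUE),
               max_ma = suppressWarnings(max(g$t_ma, na.rm = TRUE)),
               stringsAsFactors = FALSE)))
  rownames(sm) <- NULL
  list(elements = per, summary = sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
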