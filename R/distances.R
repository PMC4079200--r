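#' Tally transitions and transversions between two aligned sequences
#'
#' Sites carrying a gap or `N` in either row are excluded (pairwise
#' deletion). Transitions are A<->G and C<->T; every other difference among
#' A,C,G,T is a transversion. The returned object retains the per-site
#' classification so distance estimators can bootstrap over columns, plus
#' the mean G+C fraction of the pair over compared sites (theta for the
#' Tamura 3-parameter model).
#'
#' @param seqA,seqB Equal-length aligned DNA strings.
#' @return Object of class `substitution_counts` with fields `P` (transition
#'   proportion), `Q` (transversion proportion), `n_sites`, `gc`, and
#'   `site_class` (factor `same`/`ti`/`tv` per compared site).
#' @export
#' @examples
#' count_substitutions("ACGT", "GCGT")  # one transition
count_substitutions <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB))
    stop("aligned sequences must have equal length")
  a <- strsplit(normalize_dna(seqA), "", fixed = TRUE)[[1]]
  b <- strsplit(normalize_dna(seqB), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  ok <- a %in% acgt & b %in% acgt
  if (!any(ok)) stop("zero comparable sites after pairwise deletion")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ti <- diff & (purine[a] == purine[b])
  cls <- factor(ifelse(!diff, "same", ifelse(ti, "ti", "tv")),
                levels = c("same", "ti", "tv"))
  n <- length(a)
  structure(list(P = sum(cls == "ti") / n, Q = sum(cls == "tv") / n,
                 n_sites = n,
                 gc = mean(c(a, b) %in% c("G", "C")),
                 site_class = cls,
                 site_gc = (a %in% c("G", "C")) + (b %in% c("G", "C"))),
            class = "substitution_counts")
}

#' @export
print.substitution_counts <- function(x, ...) {
  cat(sprintf("substitution counts: P=%.4f Q=%.4f over %d sites (GC %.3f)\n",
              x$P, x$Q, x$n_sites, x$gc))
  invisible(x)
}

#' Jukes-Cantor distance from a mismatch proportion
#'
#' `d = -(3/4) log(1 - 4p/3)`; saturates at `p >= 0.75`.
#' @param p_mismatch Proportion of mismatching sites, in `[0, 0.75)`.
#' @return Corrected substitutions per site.
#' @export
jc_distance <- function(p_mismatch) {
  if (any(p_mismatch < 0)) stop("negative mismatch proportion")
  if (any(p_mismatch >= 0.75))
    stop("Jukes-Cantor saturation: p >= 0.75")
  -0.75 * log(1 - 4 * p_mismatch / 3)
}

# closed forms on (P, Q[, gc]); used by estimators and their bootstraps
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0) stop("K2P saturation: 1 - 2P - Q <= 0")
  if (w2 <= 0) stop("K2P saturation: 1 - 2Q <= 0")
  -0.5 * log(w1) - 0.25 * log(w2)
}

t3p_from_pq <- function(P, Q, gc) {
  h <- 2 * gc * (1 - gc)
  if (h <= 0) stop("T3P degenerate base composition: GC fraction is 0 or 1")
  w1 <- 1 - P / h - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0) stop("T3P saturation: 1 - P/h - Q <= 0")
  if (w2 <= 0) stop("T3P saturation: 1 - 2Q <= 0")
  -h * log(w1) - 0.5 * (1 - h) * log(w2)
}

new_distance_estimate <- function(k, se_k, model, n_sites) {
  structure(list(k = k, se_k = se_k, model = model, n_sites = n_sites),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("%s distance: k = %.5f%s over %d sites\n", x$model, x$k,
              if (is.na(x$se_k)) "" else sprintf(" +/- %.5f", x$se_k),
              x$n_sites))
  invisible(x)
}

boot_pq_distance <- function(counts, fun, boot_reps, seed) {
  if (boot_reps <= 0) return(NA_real_)
  cls <- as.integer(counts$site_class)   # 1 same, 2 ti, 3 tv
  gc2 <- counts$site_gc                  # per-site GC count (0..2)
  n <- counts$n_sites
  with_seed(seed, {
    ks <- vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      ci <- cls[idx]
      tryCatch(fun(mean(ci == 2L), mean(ci == 3L), sum(gc2[idx]) / (2 * n)),
               error = function(e) NA_real_)
    }, numeric(1))
    stats::sd(ks[is.finite(ks)])
  })
}

#' Kimura 2-parameter distance
#'
#' `k = -(1/2) log(1-2P-Q) - (1/4) log(1-2Q)`. The standard error is a
#' bootstrap over alignment columns (resampling the per-site
#' transition/transversion classification), 500 replicates by default.
#'
#' @param counts A [count_substitutions()] result.
#' @param boot_reps Bootstrap replicates for the SE (0 for none).
#' @param seed RNG seed for the bootstrap.
#' @return A `distance_estimate` (fields `k`, `se_k`, `model`, `n_sites`).
#' @export
k2p_distance <- function(counts, boot_reps = 500L, seed = NULL) {
  stopifnot(inherits(counts, "substitution_counts"))
  k <- k2p_from_pq(counts$P, counts$Q)
  se <- boot_pq_distance(counts, function(P, Q, gc) k2p_from_pq(P, Q),
                         boot_reps, seed)
  new_distance_estimate(k, se, "K2P", counts$n_sites)
}

#' Tamura 3-parameter distance
#'
#' K2P with a G+C-content correction: with `h = 2 gc (1-gc)`,
#' `k = -h log(1 - P/h - Q) - (1/2)(1-h) log(1-2Q)`. Reduces to K2P at
#' `gc = 0.5`.
#'
#' @inheritParams k2p_distance
#' @return A `distance_estimate`.
#' @export
t3p_distance <- function(counts, boot_reps = 500L, seed = NULL) {
  stopifnot(inherits(counts, "substitution_counts"))
  k <- t3p_from_pq(counts$P, counts$Q, counts$gc)
  se <- boot_pq_distance(counts, t3p_from_pq, boot_reps, seed)
  new_distance_estimate(k, se, "T3P", counts$n_sites)
}

#' Pairwise distance matrix from an alignment
#'
#' Pairwise deletion per pair. Any saturated pair is an error naming the
#' offending pair.
#'
#' @param m An [msa()].
#' @param model `"p"`, `"jc"`, `"k2p"` or `"t3p"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
distance_matrix <- function(m, model = c("t3p", "k2p", "jc", "p")) {
  model <- match.arg(model)
  stopifnot(inherits(m, "msa"))
  ids <- names(m)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    cs <- count_substitutions(m[[i]], m[[j]])
    d <- tryCatch(switch(model,
                         p   = cs$P + cs$Q,
                         jc  = jc_distance(cs$P + cs$Q),
                         k2p = k2p_from_pq(cs$P, cs$Q),
                         t3p = t3p_from_pq(cs$P, cs$Q, cs$gc)),
                  error = function(e)
                    stop("pair ", ids[i], "/", ids[j], ": ",
                         conditionMessage(e), call. = FALSE))
    D[i, j] <- D[j, i] <- d
  }
  D
}
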