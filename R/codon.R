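# Nei-Gojobori (1986-style) synonymous / nonsynonymous machinery.
#
# Site counting: at each codon position the synonymous-site fraction is the
# fraction of synonymous changes among *sense* single-nucleotide changes
# (changes creating a stop codon are excluded from numerator and
# denominator), so S + N = 3 x codons always holds. Differences between
# codons differing at d positions are averaged over the d! single-step
# pathways that avoid stop-codon intermediates; if every pathway passes
# through a stop, the unweighted average over all pathways is used.

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

codon_tables <- function() {
  if (!is.null(.retroclock_cache$codon)) return(.retroclock_cache$codon)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  bases <- c("A", "C", "G", "T")
  sense <- codons[aa != "*"]
  aa_of <- setNames(aa, codons)

  # fractional synonymous sites per sense codon
  syn_sites <- vapply(sense, function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    s <- 0
    for (pos in 1:3) {
      num <- 0L; den <- 0L
      for (b in setdiff(bases, ch[pos])) {
        alt <- ch; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (aa_of[[alt]] == "*") next
        den <- den + 1L
        if (aa_of[[alt]] == aa_of[[cd]]) num <- num + 1L
      }
      if (den > 0L) s <- s + num / den
    }
    s
  }, numeric(1))

  # pathway-averaged synonymous/nonsynonymous difference counts
  ns <- length(sense)
  SD <- matrix(0, ns, ns, dimnames = list(sense, sense))
  ND <- SD
  split1 <- strsplit(sense, "", fixed = TRUE)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    c1 <- split1[[i]]; c2 <- split1[[j]]
    dpos <- which(c1 != c2)
    if (length(dpos) == 1L) {
      syn <- aa_of[[sense[i]]] == aa_of[[sense[j]]]
      SD[i, j] <- as.numeric(syn); ND[i, j] <- as.numeric(!syn)
      next
    }
    paths <- all_permutations(dpos)
    res <- vapply(paths, function(ord) {
      cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
      for (step in seq_along(ord)) {
        nxt <- cur; nxt[ord[step]] <- c2[ord[step]]
        a1 <- aa_of[[paste(cur, collapse = "")]]
        a2 <- aa_of[[paste(nxt, collapse = "")]]
        if (identical(a1, a2)) sd <- sd + 1 else nd <- nd + 1
        if (a2 == "*" && step < length(ord)) valid <- FALSE
        cur <- nxt
      }
      c(sd, nd, valid)
    }, numeric(3))
    use <- res[3, ] == 1
    if (!any(use)) use <- rep(TRUE, ncol(res))
    SD[i, j] <- mean(res[1, use]); ND[i, j] <- mean(res[2, use])
  }
  .retroclock_cache$codon <- list(sense = sense, aa = aa_of,
                                  syn_sites = syn_sites, SD = SD, ND = ND)
  .retroclock_cache$codon
}

# per-codon-pair component vectors for two in-frame sequences; codon pairs
# with gaps, Ns or stop codons are flagged invalid (pairwise deletion)
codon_pair_components <- function(seqA, seqB) {
  seqA <- normalize_dna(seqA); seqB <- normalize_dna(seqB)
  if (nchar(seqA) != nchar(seqB)) stop("sequences must have equal length")
  if (nchar(seqA) %% 3L != 0L) stop("length must be divisible by 3 (in-frame)")
  tb <- codon_tables()
  starts <- seq(1L, nchar(seqA), by = 3L)
  ca <- substring(seqA, starts, starts + 2L)
  cb <- substring(seqB, starts, starts + 2L)
  valid <- ca %in% tb$sense & cb %in% tb$sense
  s <- sd <- nd <- numeric(length(ca))
  ia <- match(ca[valid], tb$sense); ib <- match(cb[valid], tb$sense)
  s[valid] <- (tb$syn_sites[ia] + tb$syn_sites[ib]) / 2
  sd[valid] <- tb$SD[cbind(ia, ib)]
  nd[valid] <- tb$ND[cbind(ia, ib)]
  list(s = s, n = ifelse(valid, 3 - s, 0), sd = sd, nd = nd, valid = valid)
}

ng_from_components <- function(cmp, idx = NULL) {
  if (!is.null(idx)) {
    S <- sum(cmp$s[idx]); N <- sum(cmp$n[idx])
    Sd <- sum(cmp$sd[idx]); Nd <- sum(cmp$nd[idx])
  } else {
    S <- sum(cmp$s); N <- sum(cmp$n)
    Sd <- sum(cmp$sd); Nd <- sum(cmp$nd)
  }
  if (S <= 0) stop("no synonymous sites: dS undefined")
  if (N <= 0) stop("no nonsynonymous sites: dN undefined")
  c(dS = jc_distance(Sd / S), dN = jc_distance(Nd / N),
    S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Nei-Gojobori codon distance (Jukes-Cantor corrected)
#'
#' Computes per-site synonymous (`dS`) and nonsynonymous (`dN`) distances
#' between two in-frame aligned coding sequences. Fractional synonymous
#' sites come from single-step mutational fates under the standard genetic
#' code; codons differing at several positions are resolved by averaging all
#' mutational pathways that avoid stop codons. Proportions are corrected
#' with the Jukes-Cantor formula, and standard errors come from a bootstrap
#' over codons (500 replicates by default). Codon pairs containing gaps,
#' `N`s or stop codons are excluded pairwise.
#'
#' @param seqA,seqB Equal-length, in-frame aligned coding sequences.
#' @param boot_reps Bootstrap replicates for SEs (0 for none).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `codon_distance`: `dS`, `dN`, `se_dS`, `se_dN`,
#'   `omega` (`NA` when `dS == 0`), and `counts` (S, N, Sd, Nd,
#'   codons_compared).
#' @export
nei_gojobori <- function(seqA, seqB, boot_reps = 500L, seed = NULL) {
  cmp <- codon_pair_components(seqA, seqB)
  if (!any(cmp$valid)) stop("no comparable codons after pairwise deletion")
  est <- ng_from_components(cmp)
  se <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    ncod <- length(cmp$s)
    se <- with_seed(seed, {
      reps <- vapply(seq_len(boot_reps), function(r) {
        idx <- sample.int(ncod, ncod, replace = TRUE)
        tryCatch(ng_from_components(cmp, idx)[1:2],
                 error = function(e) c(NA_real_, NA_real_))
      }, numeric(2))
      apply(reps, 1L, stats::sd, na.rm = TRUE)
    })
  }
  new_codon_distance(est, se, sum(cmp$valid))
}

new_codon_distance <- function(est, se, codons_compared) {
  dS <- unname(est["dS"]); dN <- unname(est["dN"])
  structure(list(
    dS = dS, dN = dN, se_dS = se[1], se_dN = se[2],
    omega = if (dS > 0) dN / dS else NA_real_,
    counts = list(S = unname(est["S"]), N = unname(est["N"]),
                  Sd = unname(est["Sd"]), Nd = unname(est["Nd"]),
                  codons_compared = codons_compared)),
    class = "codon_distance")
}

#' @export
print.codon_distance <- function(x, ...) {
  cat(sprintf("dS = %.4f%s, dN = %.4f%s, dN/dS = %s (%d codons)\n",
              x$dS, if (is.na(x$se_dS)) "" else sprintf(" +/- %.4f", x$se_dS),
              x$dN, if (is.na(x$se_dN)) "" else sprintf(" +/- %.4f", x$se_dN),
              if (is.na(x$omega)) "undefined" else sprintf("%.3f", x$omega),
              x$counts$codons_compared))
  invisible(x)
}

#' Mean between-group synonymous distance (ks)
#'
#' Arithmetic mean of pairwise Nei-Gojobori `dS` over all between-group
#' sequence pairs of an in-frame alignment, with a standard error from a
#' bootstrap over codon columns (the same resampled columns applied to
#' every pair within a replicate). Saturated pairs are excluded with a
#' warning and their count is reported.
#'
#' @param m An in-frame [msa()].
#' @param ids_a,ids_b Disjoint, non-empty id sets naming the two groups.
#' @param boot_reps Bootstrap replicates (0 for none).
#' @param seed RNG seed.
#' @return A `codon_distance` whose `dS`/`dN` are between-group means;
#'   attribute `n_pairs` gives used pairs, `n_excluded` saturated ones.
#' @export
group_mean_ks <- function(m, ids_a, ids_b, boot_reps = 500L, seed = NULL) {
  stopifnot(inherits(m, "msa"), length(ids_a) >= 1L, length(ids_b) >= 1L)
  if (length(intersect(ids_a, ids_b)))
    stop("groups must be disjoint")
  missing <- setdiff(c(ids_a, ids_b), names(m))
  if (length(missing)) stop("ids not in alignment: ",
                            paste(missing, collapse = ", "))
  pairs <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
  cmps <- lapply(seq_len(nrow(pairs)),
                 function(i) codon_pair_components(m[[pairs$a[i]]],
                                                  m[[pairs$b[i]]]))
  ests <- lapply(cmps, function(cmp)
    tryCatch(ng_from_components(cmp), error = function(e) NULL))
  ok <- !vapply(ests, is.null, logical(1))
  n_excl <- sum(!ok)
  if (n_excl > 0)
    warning(n_excl, " saturated/undefined pair(s) excluded from group mean")
  if (!any(ok)) stop("all between-group pairs saturated")
  est_mat <- do.call(rbind, ests[ok])
  est <- colMeans(est_mat)
  se <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    ncod <- length(cmps[[1]]$s)
    keep <- which(ok)
    se <- with_seed(seed, {
      reps <- vapply(seq_len(boot_reps), function(r) {
        idx <- sample.int(ncod, ncod, replace = TRUE)
        vals <- vapply(keep, function(i)
          tryCatch(ng_from_components(cmps[[i]], idx)[1:2],
                   error = function(e) c(NA_real_, NA_real_)), numeric(2))
        rowMeans(vals, na.rm = TRUE)
      }, numeric(2))
      apply(reps, 1L, stats::sd, na.rm = TRUE)
    })
  }
  out <- new_codon_distance(est, se,
                            round(mean(vapply(cmps[ok],
                                              function(c) sum(c$valid),
                                              numeric(1)))))
  attr(out, "n_pairs") <- sum(ok)
  attr(out, "n_excluded") <- n_excl
  out
}
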