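#' @export
`[.msa` <- function(x, i) {
  out <- unclass(x)[i]
  if (anyNA(names(out))) stop("unknown msa row id")
  msa(out)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in the
#' Q-minimum are broken deterministically by the lexicographically lowest
#' index pair. Negative branch lengths are clamped to zero; the number of
#' clamping events is recorded in the `clamped` attribute. The result is an
#' unrooted `ape::phylo` with a basal trifurcation, so path distances on an
#' additive input matrix reproduce it exactly.
#'
#' @param D Symmetric numeric matrix with zero diagonal and dimnames.
#' @return An `ape` `phylo` object (attribute `clamped` = count of clamped
#'   negative branch lengths).
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (anyNA(D) || any(!is.finite(D))) stop("distance matrix contains NaN/Inf")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  frag <- labs
  d <- D
  clamped <- 0L
  bl <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; x <- 0 }
    sprintf("%.12g", x)
  }
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hits[order(hits[, 1], hits[, 2])[1], ]
    i <- hit[1]; j <- hit[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(vi), frag[j], bl(vj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], bl(v1), frag[2], bl(v2), frag[3], bl(v3))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

# canonical bipartition keys; one per internal node (NA for trivial splits)
node_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  pp <- ape::prop.part(tree)
  vapply(pp, function(s) {
    inset <- tips %in% tree$tip.label[s]
    if (inset[1]) inset <- !inset
    sz <- sum(inset)
    if (sz < 2L || sz > ntip - 2L) return(NA_character_)
    paste(tips[inset], collapse = "|")
  }, character(1))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the full-data NJ tree from the alignment under the chosen distance
#' model, then resamples alignment columns with replacement `n_reps` times
#' (1,000 by default); the support of each internal edge is the percentage
#' of successful replicates whose NJ tree contains the same bipartition.
#' Replicates in which any pair saturates are dropped and counted.
#' Rows are sorted by id first, so supports do not depend on input order.
#'
#' @param m An [msa()] with at least 4 rows.
#' @param model Distance model (see [distance_matrix()]).
#' @param n_reps Bootstrap replicates.
#' @param seed RNG seed.
#' @return The full-data `phylo` with `node.label` set to rounded percent
#'   supports; attributes `dropped_replicates` and `support` (named vector).
#' @export
bootstrap_support <- function(m, model = "t3p", n_reps = 1000L, seed = NULL) {
  stopifnot(inherits(m, "msa"), length(m) >= 4L)
  m <- m[order(names(m))]
  full <- nj_tree(distance_matrix(m, model))
  keys <- node_bipartitions(full)
  counts <- setNames(rep(0L, length(keys)), keys)
  mat <- msa_matrix(m)
  nc <- ncol(mat)
  dropped <- 0L
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(nc, nc, replace = TRUE)
      rm <- matrix_msa(mat[, idx, drop = FALSE])
      tr <- tryCatch(nj_tree(distance_matrix(rm, model)),
                     error = function(e) NULL)
      if (is.null(tr)) { dropped <- dropped + 1L; next }
      bk <- node_bipartitions(tr)
      hit <- !is.na(keys) & keys %in% bk
      counts[hit] <- counts[hit] + 1L
    }
    used <- n_reps - dropped
    support <- ifelse(is.na(keys), NA_real_, 100 * counts / max(used, 1L))
    full$node.label <- ifelse(is.na(support), "",
                              as.character(round(support)))
    attr(full, "support") <- support
    attr(full, "dropped_replicates") <- dropped
    full
  })
}

#' Assign a query element to a reference subfamily
#'
#' The query (already in reference-alignment coordinates) is assigned the
#' label of the reference group with the smallest mean Tamura 3-parameter
#' distance; the margin is the runner-up mean minus the best. A margin
#' below `threshold` yields `"unclassified"`.
#'
#' @param query_seq Aligned query sequence (same width as the reference
#'   alignment).
#' @param reference_msa An [msa()] of reference sequences.
#' @param reference_labels Character vector of group labels, one per
#'   reference row.
#' @param threshold Minimum winning margin (substitutions/site).
#' @param min_coverage Minimum fraction of alignment columns where the
#'   query is ungapped.
#' @return List with `label`, `margin`, and the per-group `means`.
#' @export
assign_subfamily <- function(query_seq, reference_msa, reference_labels,
                             threshold = 0.01, min_coverage = 0.5) {
  stopifnot(inherits(reference_msa, "msa"),
            length(reference_labels) == length(reference_msa))
  query_seq <- normalize_dna(query_seq)
  width <- nchar(reference_msa[[1]])
  if (nchar(query_seq) != width)
    stop("query must be aligned to the reference alignment (equal width)")
  qchars <- strsplit(query_seq, "", fixed = TRUE)[[1]]
  if (mean(qchars %in% c("A", "C", "G", "T")) < min_coverage)
    stop("query covers < ", round(100 * min_coverage),
         "% of the reference region")
  dists <- vapply(seq_along(reference_msa), function(i) {
    tryCatch({
      cs <- count_substitutions(query_seq, reference_msa[[i]])
      t3p_from_pq(cs$P, cs$Q, cs$gc)
    }, error = function(e) Inf)
  }, numeric(1))
  means <- vapply(split(dists, reference_labels), mean, numeric(1))
  o <- order(means)
  margin <- if (length(means) > 1L) means[o[2]] - means[o[1]] else Inf
  label <- if (margin < threshold) "unclassified" else names(means)[o[1]]
  list(label = label, margin = unname(margin), means = means)
}
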