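# shared nucleotide scoring matrix for pairwise alignments
ntmat <- function() {
  if (is.null(.retroclock_cache$ntmat))
    .retroclock_cache$ntmat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE, type = "DNA")
  .retroclock_cache$ntmat
}

#' Sliding-window similarity profile (SimPlot-style)
#'
#' Percent identity of a query to each reference over moving windows of
#' alignment columns (defaults: window 200, step 20). Within a window only
#' positions ungapped and unambiguous in both the query and that reference
#' are compared; a window is reported for a reference only when at least
#' half of its columns are comparable.
#'
#' @param m An [msa()].
#' @param query_id Query row id.
#' @param ref_ids Reference row ids.
#' @param window,step Window size and step, in alignment columns.
#' @return Object of class `similarity_profile`: `centers` (window center
#'   columns, 1-based), `identity` and `n_compared` matrices (windows x
#'   references; `NA` where not comparable), plus a `query_coord` map from
#'   alignment column to ungapped query coordinate.
#' @export
similarity_profile <- function(m, query_id, ref_ids, window = 200L,
                               step = 20L) {
  stopifnot(inherits(m, "msa"))
  ids <- c(query_id, ref_ids)
  if (!all(ids %in% names(m))) stop("ids not in alignment")
  if (length(ref_ids) < 1L) stop("need at least one reference")
  W <- nchar(m[[1]])
  if (window > W) stop("window exceeds alignment length")
  mat <- msa_matrix(m)
  q <- mat[query_id, ]
  acgt <- c("A", "C", "G", "T")
  starts <- seq(1L, W - window + 1L, by = step)
  centers <- starts + window %/% 2L
  idm <- ncm <- matrix(NA_real_, length(starts), length(ref_ids),
                       dimnames = list(NULL, ref_ids))
  for (r in seq_along(ref_ids)) {
    rr <- mat[ref_ids[r], ]
    comp <- (q %in% acgt) & (rr %in% acgt)
    mt <- comp & (q == rr)
    ccomp <- cumsum(comp); cmt <- cumsum(mt)
    nc <- ccomp[starts + window - 1L] - c(0, ccomp)[starts]
    nm <- cmt[starts + window - 1L] - c(0, cmt)[starts]
    ok <- nc >= window / 2
    idm[ok, r] <- 100 * nm[ok] / nc[ok]
    ncm[, r] <- nc
  }
  if (all(is.na(idm))) stop("no comparable windows")
  structure(list(query = query_id, refs = ref_ids,
                 window = as.integer(window), step = as.integer(step),
                 centers = centers, identity = idm, n_compared = ncm,
                 query_coord = cumsum(q != "-")),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("similarity profile: %s vs %d reference(s), %d windows (%d/%d)\n",
              x$query, length(x$refs), length(x$centers), x$window, x$step))
  invisible(x)
}

#' Call recombination breakpoints from a similarity profile
#'
#' Each window is assigned to its nearest reference; windows whose winning
#' margin is below `margin` percentage points (or that are not comparable)
#' are `ambiguous`. A breakpoint is emitted where the assignment switches
#' and the new assignment persists for at least `min_run` informative
#' windows; shorter excursions are treated as noise.
#'
#' @param profile A [similarity_profile()] with >= 2 references.
#' @param min_run Persistence (informative windows) required to accept a
#'   switch.
#' @param margin Minimum identity margin (percentage points) for an
#'   unambiguous window.
#' @return Object of class `mosaic_call`: per-window `labels`, `segments`
#'   data frame, `breakpoints` (alignment columns) and
#'   `breakpoints_query` (ungapped query coordinates).
#' @export
call_breakpoints <- function(profile, min_run = 3L, margin = 2) {
  stopifnot(inherits(profile, "similarity_profile"))
  if (length(profile$refs) < 2L) stop("need at least 2 references")
  idm <- profile$identity
  labels <- rep("ambiguous", nrow(idm))
  margins <- rep(NA_real_, nrow(idm))
  for (w in seq_len(nrow(idm))) {
    v <- idm[w, ]
    if (sum(is.finite(v)) < 2L) next
    o <- order(v, decreasing = TRUE)
    mg <- v[o[1]] - v[o[2]]
    margins[w] <- mg
    if (mg >= margin) labels[w] <- colnames(idm)[o[1]]
  }
  inf <- which(labels != "ambiguous")
  if (!length(inf)) stop("all windows ambiguous")
  r <- rle(labels[inf])
  keep <- r$lengths >= min_run
  if (!any(keep)) stop("no assignment persists for min_run windows")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- data.frame(label = r$values[keep],
                     from = inf[starts[keep]], to = inf[ends[keep]])
  # merge consecutive confirmed segments with identical label
  merged <- segs[1, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1]) {
    if (segs$label[i] == merged$label[nrow(merged)])
      merged$to[nrow(merged)] <- segs$to[i]
    else merged <- rbind(merged, segs[i, ])
  }
  bp <- integer(0)
  if (nrow(merged) > 1L)
    bp <- vapply(seq_len(nrow(merged) - 1L), function(i) {
      a <- profile$centers[merged$to[i]]
      b <- profile$centers[merged$from[i + 1L]]
      as.integer(round((a + b) / 2))
    }, integer(1))
  seg_df <- data.frame(
    label = merged$label,
    start_col = profile$centers[merged$from],
    end_col = profile$centers[merged$to],
    mean_margin = vapply(seq_len(nrow(merged)), function(i)
      mean(margins[merged$from[i]:merged$to[i]], na.rm = TRUE), numeric(1)))
  structure(list(query = profile$query, labels = labels,
                 segments = seg_df, breakpoints = bp,
                 breakpoints_query = profile$query_coord[pmax(bp, 1L)]),
            class = "mosaic_call")
}

#' @export
print.mosaic_call <- function(x, ...) {
  cat(sprintf("mosaic call for %s: %d segment(s)", x$query,
              if (!is.null(x$segments)) nrow(x$segments) else length(x$labels)))
  if (length(x$breakpoints))
    cat(", breakpoints at column(s) ", paste(x$breakpoints, collapse = ", "))
  cat("\n")
  if (is.null(x$segments)) cat("  ", paste(x$labels, collapse = ""), "\n")
  invisible(x)
}

#' Subdomain parental (A/B) typing of putative recombinants
#'
#' The alignment is cut into subalignments at `boundaries` (the classical
#' layout subdivides an element alignment into 13 LTR/polyprotein-domain
#' segments). Within each segment every query is labeled `A` or `B` by its
#' smaller mean p-distance to the parent-A or parent-B group; ties and
#' segments with fewer than `min_cols` comparable columns are `ambiguous`.
#'
#' @param m An [msa()].
#' @param parentA_ids,parentB_ids Ids of the two parental groups.
#' @param boundaries Strictly increasing segment start columns, beginning
#'   at 1 (segments run to the next start minus one; the last to the end).
#' @param query_ids Ids to type (default: all non-parent rows).
#' @param min_cols Minimum comparable columns per segment.
#' @return Named list of `mosaic_call` objects, one per query, each with a
#'   `labels` vector over segments (`"A"`/`"B"`/`"ambiguous"`) and per-
#'   segment `margin` (|dA - dB|).
#' @export
subdomain_typing <- function(m, parentA_ids, parentB_ids, boundaries,
                             query_ids = NULL, min_cols = 20L) {
  stopifnot(inherits(m, "msa"))
  W <- nchar(m[[1]])
  if (boundaries[1] != 1L || is.unsorted(boundaries, strictly = TRUE) ||
      max(boundaries) > W)
    stop("boundaries must be strictly increasing starts beginning at 1")
  if (is.null(query_ids))
    query_ids <- setdiff(names(m), c(parentA_ids, parentB_ids))
  mat <- msa_matrix(m)
  acgt <- c("A", "C", "G", "T")
  seg_start <- boundaries
  seg_end <- c(boundaries[-1] - 1L, W)
  mean_pdist <- function(q, ids, cols) {
    d <- vapply(ids, function(id) {
      rr <- mat[id, cols]
      comp <- (q %in% acgt) & (rr %in% acgt)
      if (sum(comp) == 0L) return(c(NA_real_, 0))
      c(mean(q[comp] != rr[comp]), sum(comp))
    }, numeric(2))
    list(d = mean(d[1, ], na.rm = TRUE), ncomp = mean(d[2, ]))
  }
  out <- lapply(query_ids, function(qid) {
    q <- mat[qid, ]
    labs <- character(length(seg_start))
    marg <- numeric(length(seg_start))
    for (s in seq_along(seg_start)) {
      cols <- seg_start[s]:seg_end[s]
      a <- mean_pdist(q[cols], parentA_ids, cols)
      b <- mean_pdist(q[cols], parentB_ids, cols)
      if (!is.finite(a$d) || !is.finite(b$d) ||
          min(a$ncomp, b$ncomp) < min_cols) {
        if (min(a$ncomp, b$ncomp) < min_cols)
          warning("segment ", s, " of ", qid,
                  ": fewer than ", min_cols, " comparable columns")
        labs[s] <- "ambiguous"; marg[s] <- NA_real_
      } else if (a$d == b$d) {
        labs[s] <- "ambiguous"; marg[s] <- 0
      } else {
        labs[s] <- if (a$d < b$d) "A" else "B"
        marg[s] <- abs(a$d - b$d)
      }
    }
    structure(list(query = qid, labels = labs, margin = marg,
                   segments = NULL,
                   breakpoints = seg_start[-1][labs[-length(labs)] !=
                                                labs[-1]]),
              class = "mosaic_call")
  })
  setNames(out, query_ids)
}

#' Percent identity of two unaligned sequences
#'
#' Global (Needleman-Wunsch) alignment with match 1, mismatch -1, gap open
#' -4, gap extend -1; identity is matches over aligned columns (dual-gap
#' columns cannot occur in a global pairwise alignment).
#'
#' @param seqA,seqB DNA strings.
#' @return List with `identity` (percent) and `aligned_length`.
#' @export
pairwise_identity <- function(seqA, seqB) {
  if (!nchar(seqA) || !nchar(seqB)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(normalize_dna(seqA), normalize_dna(seqB),
                                      type = "global",
                                      substitutionMatrix = ntmat(),
                                      gapOpening = 4, gapExtension = 1)
  a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  list(identity = 100 * sum(a == b & a != "-") / length(a),
       aligned_length = length(a))
}
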