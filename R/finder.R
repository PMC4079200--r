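#' Parameters for structural element discovery
#'
#' @param kmer Anchor k-mer size.
#' @param min_coverage Minimum fraction of the query spanned by a chain of
#'   anchors for a candidate to be reported.
#' @param min_ltr Minimum LTR length (nt).
#' @param min_ltr_identity Minimum LTR-pair identity (fraction).
#' @param max_tsd_mismatch Maximum mismatches between the two 5-bp target
#'   site duplications (the structural rule for intact insertions).
#' @param diag_band Diagonal tolerance when chaining anchors.
#' @param max_anchor_gap Maximum genome gap (nt) between chained anchors.
#' @return List of class `finder_params`. TSD length is fixed at 5.
#' @export
finder_params <- function(kmer = 13L, min_coverage = 0.5, min_ltr = 100L,
                          min_ltr_identity = 0.7, max_tsd_mismatch = 1L,
                          diag_band = 30L, max_anchor_gap = 1500L) {
  p <- list(kmer = as.integer(kmer), min_coverage = min_coverage,
            min_ltr = as.integer(min_ltr),
            min_ltr_identity = min_ltr_identity, tsd_len = 5L,
            max_tsd_mismatch = as.integer(max_tsd_mismatch),
            diag_band = as.integer(diag_band),
            max_anchor_gap = as.integer(max_anchor_gap))
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x >= 0, logical(1))))
  structure(p, class = "finder_params")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# exact k-mer anchors of query against a DNAString subject
kmer_anchors <- function(subject, query, k, max_hits_per_kmer = 25L) {
  ql <- nchar(query)
  if (ql < k) return(data.frame(qpos = integer(0), gpos = integer(0)))
  starts <- seq_len(ql - k + 1L)
  kmers <- substring(query, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  starts <- starts[ok]; kmers <- kmers[ok]
  if (!length(kmers)) return(data.frame(qpos = integer(0), gpos = integer(0)))
  uk <- unique(kmers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uk))
  hits <- Biostrings::matchPDict(pd, subject)
  qpos_by_kmer <- split(starts, match(kmers, uk))
  qout <- gout <- vector("list", length(uk))
  for (i in seq_along(uk)) {
    g <- BiocGenerics::start(hits[[i]])
    if (!length(g) || length(g) > max_hits_per_kmer) next
    qs <- qpos_by_kmer[[as.character(i)]]
    qout[[i]] <- rep(qs, each = length(g))
    gout[[i]] <- rep(g, times = length(qs))
  }
  data.frame(qpos = unlist(qout) %||% integer(0),
             gpos = unlist(gout) %||% integer(0))
}

# greedy multi-chain assembly over anchors sorted by genome position
chain_anchors <- function(anchors, params, qlen) {
  if (!nrow(anchors)) return(list())
  a <- anchors[order(anchors$gpos, anchors$qpos), ]
  a$diag <- a$gpos - a$qpos
  chains <- list()           # closed
  open <- list()             # each: list(diag, glast, gmin, gmax, qmin, qmax, n)
  for (i in seq_len(nrow(a))) {
    g <- a$gpos[i]; q <- a$qpos[i]; dg <- a$diag[i]
    # close stale chains
    if (length(open)) {
      stale <- vapply(open, function(ch) g - ch$glast > params$max_anchor_gap,
                      logical(1))
      chains <- c(chains, open[stale])
      open <- open[!stale]
    }
    placed <- FALSE
    for (j in seq_along(open)) {
      if (abs(dg - open[[j]]$diag) <= params$diag_band) {
        ch <- open[[j]]
        ch$glast <- g; ch$gmax <- max(ch$gmax, g); ch$qmin <- min(ch$qmin, q)
        ch$qmax <- max(ch$qmax, q); ch$n <- ch$n + 1L
        open[[j]] <- ch
        placed <- TRUE
        break
      }
    }
    if (!placed)
      open <- c(open, list(list(diag = dg, glast = g, gmin = g, gmax = g,
                                qmin = q, qmax = q, n = 1L)))
  }
  c(chains, open)
}

#' Scan a genome for copies of a query element
#'
#' Deterministic seed-and-chain search: exact k-mer anchors on both strands
#' are chained by diagonal consistency; chains whose anchor span covers at
#' least `min_coverage` of the query are reported as candidate intervals,
#' extrapolated to full query extent.
#'
#' @param genome Genome sequence (single string).
#' @param query Query element sequence.
#' @param params A [finder_params()].
#' @return Data frame with 1-based inclusive `start`, `end`, `strand`,
#'   `coverage`, `n_anchors`, sorted by `start`. Zero rows when nothing is
#'   found.
#' @export
scan_genome <- function(genome, query, params = finder_params()) {
  genome <- normalize_dna(genome); query <- normalize_dna(query)
  if (!nchar(query)) stop("query must be non-empty")
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), coverage = numeric(0),
                      n_anchors = integer(0))
  if (nchar(genome) < params$kmer) return(empty)
  subject <- Biostrings::DNAString(genome)
  ql <- nchar(query)
  k <- params$kmer
  res <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    chains <- chain_anchors(kmer_anchors(subject, qs, k), params, ql)
    for (ch in chains) {
      cov <- (ch$qmax + k - 1L - ch$qmin + 1L) / ql
      if (cov < params$min_coverage) next
      start <- ch$gmin - (ch$qmin - 1L)
      end <- ch$gmax + k - 1L + (ql - (ch$qmax + k - 1L))
      res[[length(res) + 1L]] <-
        data.frame(start = max(1L, start), end = min(nchar(genome), end),
                   strand = strand, coverage = cov, n_anchors = ch$n)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, -out$coverage), ]
  # drop candidates largely duplicating a better overlapping one
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prevs <- which(keep[seq_len(i - 1L)])
    if (!length(prevs)) next
    prev <- prevs[length(prevs)]
    ovl <- min(out$end[i], out$end[prev]) - out$start[i] + 1L
    if (out$start[i] <= out$end[prev] &&
        ovl > 0.5 * (out$end[i] - out$start[i] + 1L)) {
      if (out$coverage[i] > out$coverage[prev]) keep[prev] <- FALSE
      else keep[i] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the terminal repeat (LTR) pair of a candidate element
#'
#' Locally aligns the candidate's head against its tail; an LTR pair is
#' accepted when the aligned repeat is at least `min_ltr` long with
#' identity at least `min_ltr_identity`. Because LTRs terminate the
#' element, repeat ends falling within 20 nt of the candidate termini are
#' snapped to them (local alignment trims terminal mismatches).
#'
#' @param candidate_seq Candidate element sequence.
#' @param params A [finder_params()].
#' @return List with `ltr5`, `ltr3` (0-based half-open intervals),
#'   `identity` (percent) and `ok`; `ok = FALSE` with a `reason` when no
#'   acceptable terminal repeat exists.
#' @export
detect_ltrs <- function(candidate_seq, params = finder_params()) {
  s <- normalize_dna(candidate_seq)
  L <- nchar(s)
  if (L < 2L * params$min_ltr)
    return(list(ok = FALSE, reason = "candidate shorter than 2 x min LTR"))
  w <- min(L %/% 2L, 2500L)
  head_s <- substr(s, 1L, w)
  tail_off <- L - w
  tail_s <- substr(s, tail_off + 1L, L)
  al <- Biostrings::pairwiseAlignment(head_s, tail_s, type = "local",
                                      substitutionMatrix = ntmat(),
                                      gapOpening = 4, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  alen <- length(pa)
  if (alen < params$min_ltr)
    return(list(ok = FALSE, reason = "no terminal repeat of sufficient length"))
  ident <- sum(pa == pb & pa != "-") / alen
  if (ident < params$min_ltr_identity)
    return(list(ok = FALSE,
                reason = sprintf("terminal repeat identity %.2f below threshold",
                                 ident)))
  p <- al@pattern@range
  q <- al@subject@range
  ltr5 <- c(BiocGenerics::start(p) - 1L, BiocGenerics::end(p))
  ltr3 <- c(tail_off + BiocGenerics::start(q) - 1L,
            tail_off + BiocGenerics::end(q))
  if (ltr5[1] <= 20L) ltr5[1] <- 0L
  if (L - ltr3[2] <= 20L) ltr3[2] <- L
  if (ltr5[2] >= ltr3[1])
    return(list(ok = FALSE, reason = "terminal repeats overlap"))
  list(ok = TRUE, ltr5 = as.integer(ltr5), ltr3 = as.integer(ltr3),
       identity = 100 * ident)
}

#' Validate the 5-bp target site duplication of a candidate insertion
#'
#' An intact insertion duplicates the 5-bp host target site on both sides;
#' the structural rule accepts at most `max_tsd_mismatch` (default 1)
#' mismatches between the two flanking 5-mers. `N`s count as mismatches.
#'
#' @param genome Genome sequence.
#' @param start,end 1-based inclusive candidate interval.
#' @param params A [finder_params()].
#' @return List with `tsd5`, `tsd3`, `mismatches` and `pass`.
#' @export
validate_tsd <- function(genome, start, end, params = finder_params()) {
  L <- nchar(genome)
  if (start - params$tsd_len < 1L || end + params$tsd_len > L)
    return(list(tsd5 = NA_character_, tsd3 = NA_character_,
                mismatches = NA_integer_, pass = FALSE))
  t5 <- substr(genome, start - params$tsd_len, start - 1L)
  t3 <- substr(genome, end + 1L, end + params$tsd_len)
  a <- strsplit(t5, "")[[1]]; b <- strsplit(t3, "")[[1]]
  mm <- sum(a != b | a == "N" | b == "N")
  list(tsd5 = t5, tsd3 = t3, mismatches = as.integer(mm),
       pass = mm <= params$max_tsd_mismatch)
}

#' Call full-length elements in a genome
#'
#' Composes [scan_genome()], [detect_ltrs()] and [validate_tsd()]: only
#' candidates with an acceptable LTR pair and an intact 5-bp TSD are
#' returned, as [element_record()]s carrying their forward-strand genome
#' location.
#'
#' @param genome Genome sequence.
#' @param query Query element sequence.
#' @param params A [finder_params()].
#' @param contig Contig name recorded in `genome_location`.
#' @param host Host code recorded on the records.
#' @param id_prefix Prefix for generated element ids.
#' @return List of `element_record`s (possibly empty).
#' @export
call_full_length <- function(genome, query, params = finder_params(),
                             contig = "chr", host = "", id_prefix = "el") {
  genome <- normalize_dna(genome)
  cands <- scan_genome(genome, query, params)
  out <- list()
  for (i in seq_len(nrow(cands))) {
    gseq <- substr(genome, cands$start[i], cands$end[i])
    eseq <- if (cands$strand[i] == "-") revcomp(gseq) else gseq
    ltr <- detect_ltrs(eseq, params)
    if (!isTRUE(ltr$ok)) next
    tsd <- validate_tsd(genome, cands$start[i], cands$end[i], params)
    if (!tsd$pass) next
    # TSDs in element orientation
    t5 <- tsd$tsd5; t3 <- tsd$tsd3
    if (cands$strand[i] == "-") { tmp <- revcomp(t3); t3 <- revcomp(t5); t5 <- tmp }
    out[[length(out) + 1L]] <- element_record(
      id = sprintf("%s_%d", id_prefix, length(out) + 1L),
      host = host, seq = eseq, ltr5 = ltr$ltr5, ltr3 = ltr$ltr3,
      tsd5 = t5, tsd3 = t3,
      genome_location = list(contig = contig, start = cands$start[i],
                             end = cands$end[i], strand = cands$strand[i]))
  }
  out
}
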