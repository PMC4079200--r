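# Independent oracles used by the tests. Deliberately written in a
# different style from the package internals (recursive enumeration rather
# than permutation tables) so they can serve as cross-checks.

.aa <- Biostrings::GENETIC_CODE
.sense_codons <- names(.aa)[.aa != "*"]

# enumerate every ordered single-step pathway between two codons,
# returning synonymous/nonsynonymous step counts and whether the pathway
# passes through a stop-codon intermediate
enum_paths <- function(cur, target) {
  cc <- strsplit(cur, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  d <- which(cc != tc)
  if (!length(d)) return(data.frame(sd = 0, nd = 0, stopped = FALSE))
  out <- NULL
  for (p in d) {
    nxt <- cc; nxt[p] <- tc[p]
    nxt_s <- paste(nxt, collapse = "")
    syn <- .aa[[cur]] == .aa[[nxt_s]]
    sub <- enum_paths(nxt_s, target)
    sub$sd <- sub$sd + as.numeric(syn)
    sub$nd <- sub$nd + as.numeric(!syn)
    sub$stopped <- sub$stopped | (.aa[[nxt_s]] == "*" & nxt_s != target)
    out <- rbind(out, sub)
  }
  out
}

# pathway-averaged (Sd, Nd) for one codon pair: stop-avoiding pathways,
# falling back to all pathways when none avoids a stop
oracle_ng_diff <- function(c1, c2) {
  paths <- enum_paths(c1, c2)
  use <- !paths$stopped
  if (!any(use)) use <- rep(TRUE, nrow(paths))
  c(sd = mean(paths$sd[use]), nd = mean(paths$nd[use]))
}

# fraction of synonymous changes among sense changes, per position, summed
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), ch[pos])
    alt_codons <- vapply(alts, function(b) {
      x <- ch; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
    aas <- .aa[alt_codons]
    sense <- aas != "*"
    if (any(sense)) s <- s + mean(aas[sense] == .aa[[codon]])
  }
  s
}

# random ultrametric-free additive tree distances: a random topology with
# positive branch lengths and its exact leaf-to-leaf path distances
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# expected proportion of differing sites under the Kimura 2-parameter
# process (transition rate 2r/3, each transversion r/6) after `years`
k2p_expected_p <- function(rate, years) {
  b <- rate / 6; a <- 2 * rate / 3
  p_ti <- 0.25 + 0.25 * exp(-4 * b * years) - 0.5 * exp(-2 * (a + b) * years)
  p_tv <- 0.5 - 0.5 * exp(-4 * b * years)
  p_ti + p_tv
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
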