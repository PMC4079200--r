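# Forward simulator of retroelement families evolving along a host species
# tree. Substitution process: K2P-like, transition:transversion 2:1, uniform
# base frequencies; noncoding positions are sampled exactly from the Kimura
# transition probabilities at the intergenic rate, coding positions evolve by
# proposal-rejection at the synonymous rate (synonymous proposals accepted,
# nonsynonymous accepted with probability omega, stop-creating proposals
# rejected), so the synonymous clock is calibrated to r_synonymous.

BASES <- c("A", "C", "G", "T")
TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV1 <- c(A = "C", G = "C", C = "A", T = "A")
TV2 <- c(A = "T", G = "T", C = "G", T = "G")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# random open reading frame of n sense codons (no stops)
random_orf <- function(n_codons) {
  sense <- codon_tables()$sense
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

coding_domain_names <- c("ORF", "orf", "gag", "protease", "PR", "RT",
                         "RNaseH", "RH", "integrase", "INT", "pol")

#' Default full-length element template
#'
#' Builds a founder element with identical LTRs and the canonical domain
#' layout (LTR5, UTR5, ORF, UTR3-PPT, LTR3). Default sizes give a ~7.7 kb
#' element with ~1.2 kb LTRs, the scale typical of grass centromeric
#' retrotransposons.
#'
#' @param ltr_len LTR length (nt).
#' @param utr5_len,utr3_len Untranslated region lengths (nt).
#' @param orf_codons Polyprotein ORF length in codons.
#' @return List with `seq`, `domain_map` (0-based half-open intervals) and
#'   `length`.
#' @export
element_template <- function(ltr_len = 1200L, utr5_len = 600L,
                             orf_codons = 1367L, utr3_len = 599L) {
  ltr <- random_dna(ltr_len)
  orf_len <- 3L * orf_codons
  seq <- paste0(ltr, random_dna(utr5_len), random_orf(orf_codons),
                random_dna(utr3_len), ltr)
  o1 <- ltr_len + utr5_len
  total <- 2L * ltr_len + utr5_len + orf_len + utr3_len
  dm <- list(LTR5 = c(0L, ltr_len),
             UTR5 = c(ltr_len, o1),
             ORF = c(o1, o1 + orf_len),
             `UTR3-PPT` = c(o1 + orf_len, total - ltr_len),
             LTR3 = c(total - ltr_len, total))
  list(seq = seq, domain_map = dm, length = total)
}

coding_mask <- function(n, region_map) {
  mask <- rep(FALSE, n)
  if (is.null(region_map)) return(mask)
  for (nm in names(region_map)) {
    if (nm %in% coding_domain_names) {
      iv <- region_map[[nm]]
      mask[(iv[1] + 1L):iv[2]] <- TRUE
    }
  }
  mask
}

# exact Kimura sampling of end states for a vector of bases
k2p_evolve_chars <- function(chars, rate, years) {
  n <- length(chars)
  if (n == 0L || years <= 0) return(chars)
  beta <- rate / 6; alpha <- 2 * rate / 3
  t <- years
  p_ti <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * t)   # each of the two transversions
  u <- runif(n)
  out <- chars
  sel_ti <- u < p_ti
  sel_tv1 <- !sel_ti & u < p_ti + p_tv
  sel_tv2 <- !sel_ti & !sel_tv1 & u < p_ti + 2 * p_tv
  out[sel_ti] <- TI_PARTNER[chars[sel_ti]]
  out[sel_tv1] <- TV1[chars[sel_tv1]]
  out[sel_tv2] <- TV2[chars[sel_tv2]]
  out
}

# one-step K2P proposal kernel (transition 2/3, each transversion 1/6)
propose_bases <- function(chars) {
  u <- runif(length(chars))
  out <- TI_PARTNER[chars]
  sel1 <- u >= 2 / 3 & u < 5 / 6
  sel2 <- u >= 5 / 6
  out[sel1] <- TV1[chars[sel1]]
  out[sel2] <- TV2[chars[sel2]]
  unname(out)
}

#' Mutate a sequence forward in time
#'
#' Noncoding positions are resampled from the exact Kimura 2-parameter
#' transition probabilities for `r_intergenic x years` expected
#' substitutions per site (transition:transversion 2:1). Positions inside
#' coding domains of `region_map` evolve by codon proposal-rejection at the
#' synonymous rate: synonymous proposals are always accepted, nonsynonymous
#' ones with probability `omega`, stop-creating ones never.
#'
#' @param seq DNA string.
#' @param years Elapsed time in years.
#' @param region_map Named list of 0-based half-open intervals; names in
#'   `ORF`/`gag`/`RT`/... mark coding regions. `NULL` = all noncoding.
#' @param rates A [rate_config()].
#' @param omega dN/dS acceptance probability for nonsynonymous proposals.
#' @param seed Optional RNG seed.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(seq, years, region_map = NULL,
                            rates = rate_config(), omega = 0.2, seed = NULL) {
  with_seed(seed, {
    if (years <= 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    coding <- coding_mask(length(chars), region_map)
    nc <- which(!coding & chars %in% BASES)
    chars[nc] <- k2p_evolve_chars(chars[nc], rates$r_intergenic, years)
    cod <- which(coding & chars %in% BASES)
    if (length(cod)) {
      orf_start <- cod[1]  # assumes one contiguous in-frame coding block
      aa_of <- Biostrings::GENETIC_CODE
      n_events <- rpois(1L, rates$r_synonymous * years * length(cod))
      if (n_events > 0L) {
        sites <- sample(cod, n_events, replace = TRUE)
        codon_of <- (sites - orf_start) %/% 3L
        # rounds: at most one event per codon per round, in event order
        while (length(sites)) {
          first <- !duplicated(codon_of)
          s <- sites[first]
          ci <- codon_of[first]
          c0 <- orf_start + 3L * ci
          old <- paste0(chars[c0], chars[c0 + 1L], chars[c0 + 2L])
          pos_in <- s - c0
          newb <- propose_bases(chars[s])
          new <- old
          substr(new, pos_in + 1L, pos_in + 1L) <- newb
          aa_old <- unname(aa_of[old]); aa_new <- unname(aa_of[new])
          accept <- !is.na(aa_new) & aa_new != "*" &
            (aa_new == aa_old | runif(length(s)) < omega)
          chars[s[accept]] <- newb[accept]
          sites <- sites[!first]; codon_of <- codon_of[!first]
        }
      }
    }
    paste(chars, collapse = "")
  })
}

#' Insert an element into a genome with target-site duplication
#'
#' The 5-mer starting at `position` is duplicated so it flanks the element
#' on both sides, as retroviral-type integration does; the genome grows by
#' `nchar(element_seq) + 5`.
#'
#' @param genome Genome string.
#' @param element_seq Element string.
#' @param position 1-based start of the 5-bp target site.
#' @return List with `genome`, element `start`/`end` (1-based inclusive)
#'   and the duplicated `tsd`.
#' @export
insert_element <- function(genome, element_seq, position) {
  L <- nchar(genome)
  stopifnot(position >= 1L, position + 4L <= L)
  tsd <- substr(genome, position, position + 4L)
  list(genome = paste0(substr(genome, 1L, position + 4L), element_seq,
                       substr(genome, position, L)),
       start = position + 5L,
       end = position + 4L + nchar(element_seq),
       tsd = tsd)
}

#' Build a recombinant (mosaic) element from two parents
#'
#' Parents must be homologous and equal length (coordinates via their true
#' alignment). Segments alternate A, B, A, ... starting with parent A at
#' position 1; `breakpoints` are the 1-based positions where each new
#' segment starts.
#'
#' @param parentA,parentB Equal-length parent sequences.
#' @param breakpoints Strictly increasing integer positions.
#' @return List with `seq` and `truth` (data frame of segments).
#' @export
recombine <- function(parentA, parentB, breakpoints = integer(0)) {
  L <- nchar(parentA)
  stopifnot(nchar(parentB) == L)
  if (length(breakpoints)) {
    stopifnot(!is.unsorted(breakpoints, strictly = TRUE),
              all(breakpoints > 1L), all(breakpoints <= L))
  }
  cuts <- c(1L, as.integer(breakpoints), L + 1L)
  parent <- rep(c("A", "B"), length.out = length(cuts) - 1L)
  segs <- vapply(seq_len(length(cuts) - 1L), function(i)
    substr(if (parent[i] == "A") parentA else parentB,
           cuts[i], cuts[i + 1L] - 1L), character(1))
  list(seq = paste(segs, collapse = ""),
       truth = data.frame(start = cuts[-length(cuts)],
                          end = cuts[-1] - 1L, parent = parent))
}

#' Simulation configuration
#'
#' @param host_tree Newick string (branch lengths in Myr; ultrametric).
#' @param n_subfamilies Independent founder element lineages at the root.
#' @param transposition_rate New insertions per master lineage per Myr.
#' @param rates A [rate_config()].
#' @param omega dN/dS of the polyprotein ORF.
#' @param template An [element_template()]-style list (`NULL` = generate at
#'   simulation time with default sizes).
#' @param genome_length Background genome length per host (nt).
#' @param ht_events `NULL` or data frame `donor`, `recipient` (tip labels),
#'   `subfamily` (index), `time_ma`; donor and recipient must be tips and
#'   the time must fall within both terminal branches.
#' @param seed RNG seed (all simulator randomness flows from it).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(host_tree = "(A:50,B:50);", n_subfamilies = 2L,
                       transposition_rate = 0.2, rates = rate_config(),
                       omega = 0.2, template = NULL, genome_length = 30000L,
                       ht_events = NULL, seed = 1L) {
  structure(list(host_tree = host_tree,
                 n_subfamilies = as.integer(n_subfamilies),
                 transposition_rate = transposition_rate, rates = rates,
                 omega = omega, template = template,
                 genome_length = as.integer(genome_length),
                 ht_events = ht_events, seed = seed),
            class = "sim_config")
}

#' Simulate a retroelement family history along a host tree
#'
#' Master-copy model: each subfamily has one active master lineage per host
#' branch; retrotransposition copies the master, resets the two LTRs to
#' identity and stamps the true insertion time; a horizontal-transfer event
#' copies the donor master across hosts at the event time (with LTR reset,
#' as the transferred element reinserts) and replaces the recipient's
#' master for that subfamily. All copies keep accumulating substitutions
#' until the present. Outputs are bit-identical for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List: `elements` (list of [element_record()]s with genome
#'   locations), `genomes` (named character, one per host), `alignments`
#'   (per-subfamily true [msa()]s), `truth` (per-element data frame: host,
#'   subfamily, birth time in Ma, HT flag, origin), and `pair_truth`
#'   (cross-host master-pair divergence times in Ma).
#' @export
simulate_cr <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    tree <- if (inherits(config$host_tree, "phylo")) config$host_tree
            else ape::read.tree(text = config$host_tree)
    ntip <- length(tree$tip.label)
    ages <- c(setNames(rep(0, ntip), seq_len(ntip)),
              ape::branching.times(tree))
    root <- ntip + 1L
    root_age <- unname(ages[as.character(root)])
    tmpl <- config$template
    if (is.null(tmpl)) tmpl <- element_template()
    dm <- tmpl$domain_map
    ltr5 <- dm$LTR5; ltr3 <- dm$LTR3
    nsub <- config$n_subfamilies
    # independent founder lineage per subfamily, identical LTRs at root
    founders <- lapply(seq_len(nsub), function(s)
      list(seq = element_template(
             ltr_len = ltr5[2] - ltr5[1],
             utr5_len = dm$UTR5[2] - dm$UTR5[1],
             orf_codons = (dm$ORF[2] - dm$ORF[1]) %/% 3L,
             utr3_len = dm$`UTR3-PPT`[2] - dm$`UTR3-PPT`[1])$seq,
           birth = root_age, ht = FALSE))
    reset_ltrs <- function(seq) {
      paste0(substr(seq, ltr5[1] + 1L, ltr5[2]),
             substr(seq, ltr5[2] + 1L, ltr3[1]),
             substr(seq, ltr5[1] + 1L, ltr5[2]))
    }
    mut <- function(m, myr) {
      m$seq <- mutate_sequence(m$seq, myr * 1e6, region_map = dm,
                               rates = config$rates, omega = config$omega)
      m
    }

    ht <- config$ht_events
    if (!is.null(ht)) {
      stopifnot(all(c("donor", "recipient", "subfamily", "time_ma")
                    %in% names(ht)))
      for (i in seq_len(nrow(ht))) {
        di <- match(ht$donor[i], tree$tip.label)
        ri <- match(ht$recipient[i], tree$tip.label)
        if (is.na(di) || is.na(ri))
          stop("HT donor/recipient must be tip labels")
        dpar <- tree$edge[tree$edge[, 2] == di, 1]
        rpar <- tree$edge[tree$edge[, 2] == ri, 1]
        if (ht$time_ma[i] >= min(ages[as.character(dpar)],
                                 ages[as.character(rpar)]) ||
            ht$time_ma[i] <= 0)
          stop("HT time must fall within both terminal branches")
      }
    }
    transfers <- list()   # captured donor master states, keyed by event row

    copies <- list()
    descend_tips <- function(node) {
      if (node <= ntip) return(node)
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      unlist(lapply(kids, descend_tips))
    }
    subtree_has <- function(node, labels)
      any(tree$tip.label[descend_tips(node)] %in% labels)

    # walk one edge, returning the per-subfamily master states at its child
    walk_edge <- function(child, masters, t_from) {
      t_to <- unname(ages[as.character(child)])
      is_tip <- child <= ntip
      ev <- NULL
      for (s in seq_len(nsub)) {
        n <- rpois(1L, config$transposition_rate * (t_from - t_to))
        if (n > 0L)
          ev <- rbind(ev, data.frame(time = runif(n, t_to, t_from),
                                     type = "copy", sub = s, row = NA_integer_))
      }
      if (is_tip && !is.null(ht)) {
        lab <- tree$tip.label[child]
        for (i in seq_len(nrow(ht))) {
          if (ht$donor[i] == lab)
            ev <- rbind(ev, data.frame(time = ht$time_ma[i], type = "capture",
                                       sub = ht$subfamily[i], row = i))
          if (ht$recipient[i] == lab)
            ev <- rbind(ev, data.frame(time = ht$time_ma[i], type = "arrive",
                                       sub = ht$subfamily[i], row = i))
        }
      }
      if (!is.null(ev)) ev <- ev[order(-ev$time), , drop = FALSE]
      t_cur <- t_from
      for (i in seq_len(NROW(ev))) {
        dt <- t_cur - ev$time[i]
        if (dt > 0) masters <- lapply(masters, mut, myr = dt)
        t_cur <- ev$time[i]
        s <- ev$sub[i]
        if (ev$type[i] == "copy") {
          copies[[length(copies) + 1L]] <<-
            list(seq = reset_ltrs(masters[[s]]$seq), birth = t_cur,
                 node = child, sub = s)
        } else if (ev$type[i] == "capture") {
          transfers[[as.character(ev$row[i])]] <<-
            reset_ltrs(masters[[s]]$seq)
        } else {
          key <- as.character(ev$row[i])
          if (is.null(transfers[[key]]))
            stop("HT donor lineage must be simulated before the recipient ",
                 "reaches the event time (reorder hosts in the tree)")
          masters[[s]] <- list(seq = transfers[[key]], birth = t_cur,
                               ht = TRUE)
        }
      }
      if (t_cur - t_to > 0) masters <- lapply(masters, mut, myr = t_cur - t_to)
      masters
    }

    # traverse; order children so subtrees holding HT donors are walked first
    tip_states <- vector("list", ntip)
    recurse <- function(node, masters) {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      if (!is.null(ht) && length(kids) > 1L) {
        has_donor <- vapply(kids, subtree_has, logical(1), labels = ht$donor)
        has_recip <- vapply(kids, subtree_has, logical(1),
                            labels = ht$recipient)
        kids <- kids[order(!has_donor, has_recip)]
      }
      for (k in kids) {
        st <- walk_edge(k, masters, unname(ages[as.character(node)]))
        if (k <= ntip) tip_states[[k]] <<- st else recurse(k, st)
      }
    }
    recurse(root, founders)

    elements <- list()
    truth <- list()
    emit <- function(seq, host_tip, sub, birth, ht_flag, origin) {
      id <- sprintf("%s_%s_%d", format_name(sub, tree$tip.label[host_tip]),
                    origin, length(elements) + 1L)
      elements[[length(elements) + 1L]] <<- element_record(
        id = id, host = tree$tip.label[host_tip], seq = seq,
        ltr5 = ltr5, ltr3 = ltr3, domain_map = dm,
        subfamily = format_name(sub, tree$tip.label[host_tip]))
      truth[[length(truth) + 1L]] <<- data.frame(
        id = id, host = tree$tip.label[host_tip], subfamily = sub,
        birth_ma = birth, ht = ht_flag, origin = origin,
        stringsAsFactors = FALSE)
    }
    for (tip in seq_len(ntip)) {
      ms <- tip_states[[tip]]
      for (s in seq_len(nsub))
        emit(ms[[s]]$seq, tip, s, ms[[s]]$birth, isTRUE(ms[[s]]$ht), "master")
    }
    for (cp in copies) {
      for (tip in descend_tips(cp$node)) {
        # each descendant tip's copy is evolved independently from birth
        emit(mutate_sequence(cp$seq, cp$birth * 1e6, region_map = dm,
                             rates = config$rates, omega = config$omega),
             tip, cp$sub, cp$birth, FALSE, "copy")
      }
    }
    truth <- do.call(rbind, truth)

    # cross-host master-pair divergence truth
    tiplabs <- tree$tip.label
    pair_rows <- list()
    for (s in seq_len(nsub)) for (i in seq_len(max(ntip - 1L, 0)))
      for (j in seq(i + 1L, ntip)) {
        mrca <- ape::getMRCA(tree, c(tiplabs[i], tiplabs[j]))
        t <- unname(ages[as.character(mrca)])
        is_ht <- FALSE
        if (!is.null(ht)) {
          hit <- ht$subfamily == s &
            ((ht$donor == tiplabs[i] & ht$recipient == tiplabs[j]) |
             (ht$donor == tiplabs[j] & ht$recipient == tiplabs[i]))
          if (any(hit)) { t <- ht$time_ma[which(hit)[1]]; is_ht <- TRUE }
        }
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          subfamily = s, host_a = tiplabs[i], host_b = tiplabs[j],
          t_ma = t, ht = is_ht, stringsAsFactors = FALSE)
      }
    pair_truth <- do.call(rbind, pair_rows)

    # genomes: background sequence per host with elements inserted (TSDs
    # stamped by construction); element coordinates reported on the final
    # genome
    genomes <- character(0)
    for (tip in seq_len(ntip)) {
      g <- random_dna(config$genome_length)
      idx <- which(truth$host == tiplabs[tip])
      if (length(idx)) {
        repeat {
          pos <- sort(sample(seq(10L, config$genome_length - 10L),
                             length(idx)))
          if (length(pos) < 2L || min(diff(pos)) > 10L) break
        }
        elens <- vapply(elements[idx], function(e) nchar(e$seq), integer(1))
        for (m in rev(seq_along(idx))) {
          ins <- insert_element(g, elements[[idx[m]]]$seq, pos[m])
          g <- ins$genome
          elements[[idx[m]]]$tsd5 <- ins$tsd
          elements[[idx[m]]]$tsd3 <- ins$tsd
        }
        offset <- c(0L, cumsum(elens + 5L))[seq_along(idx)]
        for (m in seq_along(idx))
          elements[[idx[m]]]$genome_location <-
            list(contig = tiplabs[tip], start = pos[m] + 5L + offset[m],
                 end = pos[m] + 4L + offset[m] + elens[m], strand = "+")
      }
      genomes[tiplabs[tip]] <- g
    }

    alignments <- lapply(seq_len(nsub), function(s) {
      idx <- which(truth$subfamily == s)
      msa(setNames(vapply(elements[idx], function(e) e$seq, character(1)),
                   truth$id[idx]))
    })
    names(alignments) <- paste0("CR", seq_len(nsub))

    list(elements = elements, genomes = genomes, alignments = alignments,
         truth = truth, pair_truth = pair_truth, template = tmpl,
         config = config)
  })
}
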