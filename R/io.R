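#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased, RNA `U` is converted to `T`, and IUPAC ambiguity
#' codes other than `N` are mapped to `N` (pairwise-deletion distance methods
#' in this package treat only `N` and `-` as missing). Gap characters are
#' preserved so aligned FASTA round-trips.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are FASTA ids).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(c(a = "acgu", b = "ACGT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  seqs <- normalize_dna(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.character(records))
  if (length(records) && is.null(names(records)))
    stop("records must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# uppercase, U->T, ambiguity codes (other than N) -> N; keeps '-' and '.'->'-'
normalize_dna <- function(x) {
  x <- toupper(x)
  x <- chartr("U.", "T-", x)
  gsub("[^ACGTN-]", "N", x)
}

#' Construct a multiple sequence alignment object
#'
#' A thin container: a named character vector of equal-length aligned rows
#' over `A,C,G,T,N,-`, with class `"msa"`.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return An object of class `msa`.
#' @export
msa <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("msa rows must have unique names")
  seqs <- normalize_dna(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("msa rows must all have equal length")
  structure(seqs, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x), " sequences x ", nchar(x[[1]]), " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file as an `msa`
#' @param path Path to aligned FASTA.
#' @return An `msa` object.
#' @export
read_msa <- function(path) msa(read_fasta(path))

# msa -> character matrix (rows = sequences)
msa_matrix <- function(m) {
  mat <- do.call(rbind, strsplit(unclass(m), "", fixed = TRUE))
  rownames(mat) <- names(m)
  mat
}

matrix_msa <- function(mat) {
  msa(setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat)))
}

#' Remove problem columns from an alignment
#'
#' Mode `"single_indel"` codifies the manual cleanup of removing single
#' nucleotide in-dels: every column in which at least one row carries an
#' isolated gap (a gap run of length exactly 1 flanked by non-gap characters)
#' is dropped. Mode `"gap_fraction"` drops columns whose gap fraction
#' exceeds `f`. The returned object carries a `column_map` attribute giving,
#' for each surviving column, its 1-based index in the input alignment.
#'
#' @param m An `msa`.
#' @param mode `"single_indel"` or `"gap_fraction"`.
#' @param f Gap-fraction threshold (used by `"gap_fraction"`).
#' @return Filtered `msa` with attribute `column_map` (strictly increasing).
#' @export
strip_alignment_columns <- function(m, mode = c("single_indel", "gap_fraction"),
                                    f = 0.5) {
  mode <- match.arg(mode)
  mat <- msa_matrix(m)
  nc <- ncol(mat)
  if (nc == 0L) stop("empty alignment")
  if (mode == "single_indel") {
    bad <- rep(FALSE, nc)
    for (i in seq_len(nrow(mat))) {
      g <- mat[i, ] == "-"
      if (!any(g)) next
      r <- rle(g)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      iso <- which(r$values & r$lengths == 1L &
                     starts > 1L & ends < nc)
      if (length(iso)) bad[starts[iso]] <- TRUE
    }
    keep <- which(!bad)
  } else {
    gapfrac <- colMeans(mat == "-")
    keep <- which(gapfrac <= f)
  }
  if (!length(keep)) stop("no columns survive filtering")
  out <- matrix_msa(mat[, keep, drop = FALSE])
  attr(out, "column_map") <- keep
  out
}

#' Tripartite retrotransposon subfamily name
#'
#' Builds names of the form `CR{n}-{host}` or `CR{n}-{host}-{subgroup}`,
#' e.g. `CR1-Zm-A` for sequence variant A of the Zea mays CR1 subfamily.
#'
#' @param subfamily_no Integer subfamily number (>= 1).
#' @param host_code Abbreviated host species code (e.g. `"Zm"`, `"Sb"`).
#' @param subgroup Optional subgroup label (`"A"`, `"R1"`, ...); empty for none.
#' @return Character name.
#' @export
#' @examples
#' format_name(1, "Zm", "A")   # "CR1-Zm-A"
#' format_name(2, "Bd")        # "CR2-Bd"
format_name <- function(subfamily_no, host_code, subgroup = "") {
  stopifnot(length(subfamily_no) == 1L, subfamily_no >= 1,
            subfamily_no == as.integer(subfamily_no),
            is.character(host_code), nzchar(host_code))
  base <- sprintf("CR%d-%s", as.integer(subfamily_no), host_code)
  if (is.null(subgroup) || !nzchar(subgroup)) base
  else paste0(base, "-", subgroup)
}

#' Substitution-rate configuration
#'
#' Default rates follow common usage for grass genomes: a synonymous rate of
#' 6.5e-9 substitutions per synonymous site per year (grass adh1/2 alleles)
#' for coding-region divergence dating, and an intergenic rate of 3.3e-8
#' substitutions per site per year (maize tb1 intergenic region) for
#' LTR-divergence insertion dating.
#'
#' @param r_synonymous Synonymous substitutions/site/year.
#' @param r_intergenic Intergenic substitutions/site/year.
#' @return A list of class `rate_config`.
#' @export
rate_config <- function(r_synonymous = 6.5e-9, r_intergenic = 3.3e-8) {
  stopifnot(r_synonymous > 0, r_intergenic > 0)
  structure(list(r_synonymous = r_synonymous, r_intergenic = r_intergenic),
            class = "rate_config")
}

#' Structurally annotated full-length retroelement record
#'
#' Intervals are 0-based half-open in element coordinates (reports are
#' rendered 1-based inclusive).
#'
#' @param id Element id.
#' @param host Host species code (e.g. `"Zm"`).
#' @param seq Element DNA sequence.
#' @param ltr5,ltr3 Integer `c(start, end)` intervals of the LTRs.
#' @param tsd5,tsd3 5-character target site duplication strings.
#' @param domain_map Optional named list of intervals (LTR5, UTR5, gag, ...).
#' @param subfamily Tripartite subfamily label or `""`.
#' @param genome_location Optional list `(contig, start, end, strand)`.
#' @return An object of class `element_record`.
#' @export
element_record <- function(id, host, seq, ltr5, ltr3,
                           tsd5 = NULL, tsd3 = NULL, domain_map = NULL,
                           subfamily = "", genome_location = NULL) {
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  chk_iv <- function(iv, what) {
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > n || iv[1] >= iv[2])
      stop(what, " interval out of range for a ", n, " nt element")
    as.integer(iv)
  }
  ltr5 <- chk_iv(ltr5, "ltr5"); ltr3 <- chk_iv(ltr3, "ltr3")
  if (ltr5[2] > ltr3[1]) stop("ltr5 must precede ltr3")
  for (t in list(tsd5, tsd3))
    if (!is.null(t) && nchar(t) != 5L) stop("TSD strings must have length 5")
  if (!is.null(domain_map)) {
    ivs <- do.call(rbind, lapply(domain_map, chk_iv, what = "domain"))
    o <- order(ivs[, 1])
    if (any(ivs[o, 2][-nrow(ivs)] > ivs[o, 1][-1]))
      stop("domain intervals must be non-overlapping and ordered")
  }
  structure(list(id = id, host = host, seq = seq,
                 ltr5 = ltr5, ltr3 = ltr3, tsd5 = tsd5, tsd3 = tsd3,
                 domain_map = domain_map, subfamily = subfamily,
                 genome_location = genome_location),
            class = "element_record")
}

#' @export
print.element_record <- function(x, ...) {
  cat(sprintf("element %s [%s%s], %d nt; LTR5 %d-%d, LTR3 %d-%d (1-based)\n",
              x$id, x$host,
              if (nzchar(x$subfamily)) paste0(", ", x$subfamily) else "",
              nchar(x$seq),
              x$ltr5[1] + 1L, x$ltr5[2], x$ltr3[1] + 1L, x$ltr3[2]))
  if (!is.null(x$tsd5))
    cat(sprintf("  TSD %s / %s\n", x$tsd5, x$tsd3))
  invisible(x)
}

ltr_seqs <- function(el) {
  c(substr(el$seq, el$ltr5[1] + 1L, el$ltr5[2]),
    substr(el$seq, el$ltr3[1] + 1L, el$ltr3[2]))
}

#' Host species divergence-time table
#'
#' Symmetric lookup of species-pair divergence times in Ma. Construct from a
#' data frame (`species_a`, `species_b`, `t_ma`, optional `t_min`/`t_max`)
#' or read from TSV with [read_host_table()].
#'
#' @param df Data frame with columns `species_a`, `species_b`, `t_ma`.
#' @return Object of class `host_table`.
#' @export
host_table <- function(df) {
  stopifnot(all(c("species_a", "species_b", "t_ma") %in% names(df)))
  if (any(df$t_ma <= 0)) stop("divergence times must be > 0")
  structure(df, class = c("host_table", "data.frame"))
}

#' @rdname host_table
#' @param path Path to a TSV file with header `species_a species_b t_ma`.
#' @export
read_host_table <- function(path) {
  host_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Look up a host-pair divergence time
#'
#' @param table A [host_table()].
#' @param a,b Species codes. Lookup is symmetric; a missing pair is an error.
#' @return Divergence time in Ma.
#' @export
host_divergence <- function(table, a, b) {
  hit <- (table$species_a == a & table$species_b == b) |
         (table$species_a == b & table$species_b == a)
  if (!any(hit))
    stop("no divergence time recorded for host pair ", a, "/", b)
  table$t_ma[which(hit)[1]]
}
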