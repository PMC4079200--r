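test_that("identical ORFs give zero distances with undefined omega", {
  orf <- "ATGGCTAAGGCTTGG"
  d <- nei_gojobori(orf, orf, boot_reps = 0)
  expect_equal(d$dS, 0)
  expect_equal(d$dN, 0)
  expect_true(is.na(d$omega))
  expect_identical(selection_check(d), "undefined")
})

test_that("synonymous site fractions match the per-position oracle", {
  tb <- retroclock:::codon_tables()
  for (cd in c("TTT", "CTT", "ATG", "TGG", "TAT", "CGA", "GGG", "ATA")) {
    expect_equal(unname(tb$syn_sites[cd]), oracle_syn_sites(cd),
                 info = cd)
  }
  # fourfold-degenerate third positions contribute a full synonymous site
  expect_equal(unname(tb$syn_sites["GGG"]), 1)
  expect_equal(unname(tb$syn_sites["ATG"]), 0)  # Met: no synonymous change
})

test_that("pathway-averaged differences match the enumeration oracle on a sample", {
  tb <- retroclock:::codon_tables()
  set.seed(31)
  pairs <- cbind(sample(tb$sense, 150, TRUE), sample(tb$sense, 150, TRUE))
  # include sense pairs some of whose pathways cross stop intermediates
  pairs <- rbind(pairs, c("TGG", "TCA"), c("TGG", "AGA"), c("TAC", "TGG"),
                 c("TCA", "TTG"))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    o <- oracle_ng_diff(pairs[i, 1], pairs[i, 2])
    expect_equal(tb$SD[pairs[i, 1], pairs[i, 2]], unname(o["sd"]),
                 info = paste(pairs[i, ], collapse = "/"))
    expect_equal(tb$ND[pairs[i, 1], pairs[i, 2]], unname(o["nd"]),
                 info = paste(pairs[i, ], collapse = "/"))
  }
})

test_that("site counts conserve S + N = 3 x codons under pairwise deletion", {
  set.seed(17)
  for (rep in 1:20) {
    a <- paste(sample(.sense_codons, 60, TRUE), collapse = "")
    b <- mutate_sequence(a, runif(1, 1, 20) * 1e6,
                         region_map = list(ORF = c(0, nchar(a))))
    cmp <- retroclock:::codon_pair_components(a, b)
    expect_equal(sum(cmp$s) + sum(cmp$n), 3 * sum(cmp$valid),
                 tolerance = 1e-9)
    d <- nei_gojobori(a, b, boot_reps = 0)
    expect_equal(d$counts$S + d$counts$N, 3 * d$counts$codons_compared,
                 tolerance = 1e-9)
    expect_true(d$counts$Sd <= 3 * d$counts$codons_compared)
  }
})

test_that("codons with gaps, Ns or stops are excluded pairwise", {
  a <- "ATGAAACCC"
  b <- "ATG---CCC"
  d <- nei_gojobori(a, b, boot_reps = 0)
  expect_equal(d$counts$codons_compared, 2)
  d2 <- nei_gojobori("ATGTAACCC", "ATGCAACCC", boot_reps = 0)  # TAA = stop
  expect_equal(d2$counts$codons_compared, 2)
  expect_error(nei_gojobori("AT", "AT"), "divisible by 3")
  expect_error(nei_gojobori("---", "---"), "no comparable codons")
})

test_that("purifying selection leaves dN/dS below one in simulated ORFs", {
  below <- 0L
  for (s in 1:40) {
    set.seed(1000 + s)
    anc <- paste(sample(.sense_codons, 300, TRUE), collapse = "")
    rm <- list(ORF = c(0, nchar(anc)))
    a <- mutate_sequence(anc, 10e6, region_map = rm, omega = 0.2)
    b <- mutate_sequence(anc, 10e6, region_map = rm, omega = 0.2)
    d <- nei_gojobori(a, b, boot_reps = 0)
    if (!is.na(d$omega) && d$omega < 1) below <- below + 1L
  }
  expect_gte(below, 38L)  # >= 95% of replicates
})

test_that("codon bootstrap SEs are seed-reproducible", {
  set.seed(4)
  anc <- paste(sample(.sense_codons, 100, TRUE), collapse = "")
  b <- mutate_sequence(anc, 8e6, region_map = list(ORF = c(0, nchar(anc))))
  d1 <- nei_gojobori(anc, b, boot_reps = 200, seed = 9)
  d2 <- nei_gojobori(anc, b, boot_reps = 200, seed = 9)
  expect_identical(d1$se_dS, d2$se_dS)
  expect_identical(d1$se_dN, d2$se_dN)
  expect_gt(d1$se_dS, 0)
})

test_that("between-group mean ks equals the brute-force pair average", {
  set.seed(23)
  anc <- paste(sample(.sense_codons, 150, TRUE), collapse = "")
  rm <- list(ORF = c(0, nchar(anc)))
  g <- function() mutate_sequence(anc, 6e6, region_map = rm)
  rows <- setNames(c(g(), g(), g(), g()), c("a1", "a2", "b1", "b2"))
  m <- msa(rows)
  gm <- group_mean_ks(m, c("a1", "a2"), c("b1", "b2"), boot_reps = 0)
  manual <- mean(c(nei_gojobori(rows["a1"], rows["b1"], boot_reps = 0)$dS,
                   nei_gojobori(rows["a1"], rows["b2"], boot_reps = 0)$dS,
                   nei_gojobori(rows["a2"], rows["b1"], boot_reps = 0)$dS,
                   nei_gojobori(rows["a2"], rows["b2"], boot_reps = 0)$dS))
  expect_equal(gm$dS, manual)
  # identical groups give zero
  m0 <- msa(setNames(rep(anc, 4), c("a1", "a2", "b1", "b2")))
  expect_equal(group_mean_ks(m0, c("a1", "a2"), c("b1", "b2"),
                             boot_reps = 0)$dS, 0)
  expect_error(group_mean_ks(m, c("a1"), c("a1", "b1")), "disjoint")
})

test_that("group ks over a 10-Ma split matches the 2rT expectation", {
  set.seed(77)
  anc <- paste(sample(.sense_codons, 400, TRUE), collapse = "")
  rm <- list(ORF = c(0, nchar(anc)))
  yrs <- 10e6
  rows <- setNames(c(mutate_sequence(anc, yrs, region_map = rm),
                     mutate_sequence(anc, yrs, region_map = rm),
                     mutate_sequence(anc, yrs, region_map = rm),
                     mutate_sequence(anc, yrs, region_map = rm)),
                   c("a1", "a2", "b1", "b2"))
  gm <- group_mean_ks(msa(rows), c("a1", "a2"), c("b1", "b2"),
                      boot_reps = 200, seed = 5)
  expect_lt(abs(gm$dS - 2 * 6.5e-9 * yrs), 3 * gm$se_dS)
})
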