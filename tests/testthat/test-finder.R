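# small planted-genome fixtures built in code; coordinates tracked exactly
plant <- function(genome, elem, pos) {
  ins <- insert_element(genome, elem, pos)
  list(genome = ins$genome, start = ins$start, end = ins$end)
}

test_that("an exact planted copy is found as one spanning candidate", {
  set.seed(201)
  q <- element_template(ltr_len = 300, utr5_len = 100, orf_codons = 200,
                        utr3_len = 100)
  g <- random_seq(30000)
  p <- plant(g, q$seq, 12000)
  cand <- scan_genome(p$genome, q$seq)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, p$start)
  expect_equal(cand$end, p$end)
  expect_identical(cand$strand, "+")
})

test_that("an empty or element-free genome yields no candidates", {
  set.seed(202)
  q <- random_seq(2000)
  expect_equal(nrow(scan_genome("", q)), 0L)
  expect_equal(nrow(scan_genome(random_seq(20000), q)), 0L)
  expect_error(scan_genome(random_seq(100), ""), "query")
})

test_that("diverged copies at 85-95% identity are all recovered", {
  set.seed(203)
  q <- element_template(ltr_len = 300, utr5_len = 100, orf_codons = 300,
                        utr3_len = 100)
  g <- random_seq(100000)
  truth <- NULL
  for (i in 1:3) {
    cp <- mutate_sequence(q$seq, (0.05 + 0.05 * i) / (2 * 3.3e-8))
    p <- plant(g, cp, 20000 * i + (i - 1) * (q$length + 5))
    g <- p$genome
    truth <- rbind(truth, data.frame(start = p$start, end = p$end))
  }
  cand <- scan_genome(g, q$seq)
  expect_equal(nrow(cand), 3L)
  expect_equal(cand$start, truth$start)
  expect_equal(cand$end, truth$end)
})

test_that("LTR detection recovers intervals on clean and mutated elements", {
  set.seed(204)
  q <- element_template(ltr_len = 800, utr5_len = 300, orf_codons = 500,
                        utr3_len = 300)
  lt <- detect_ltrs(q$seq)
  expect_true(lt$ok)
  expect_equal(lt$ltr5, c(0L, 800L))
  expect_equal(lt$ltr3, c(q$length - 800L, q$length))
  expect_equal(lt$identity, 100)

  mutd <- mutate_sequence(q$seq, 0.05 / (2 * 3.3e-8))  # LTR pair k ~ 0.05
  lt2 <- detect_ltrs(mutd)
  expect_true(lt2$ok)
  expect_lte(max(abs(lt2$ltr5 - c(0, 800))), 5)
  expect_lte(max(abs(lt2$ltr3 - c(q$length - 800, q$length))), 5)

  bad <- detect_ltrs(random_seq(4000))
  expect_false(bad$ok)
})

test_that("the TSD rule accepts at most one mismatch", {
  g <- paste0("ACGTA", random_seq(100), "ACGTA")
  expect_true(validate_tsd(g, 6, 105)$pass)
  g1 <- paste0("ACGTA", random_seq(100), "ACGTT")
  v1 <- validate_tsd(g1, 6, 105)
  expect_true(v1$pass); expect_equal(v1$mismatches, 1L)
  g2 <- paste0("ACGTA", random_seq(100), "ACGGG")
  expect_false(validate_tsd(g2, 6, 105)$pass)
  # missing flank fails
  expect_false(validate_tsd(random_seq(50), 1, 40)$pass)
})

test_that("full-length calling keeps intact elements and drops broken TSDs", {
  set.seed(206)
  q <- element_template(ltr_len = 300, utr5_len = 100, orf_codons = 300,
                        utr3_len = 100)
  g <- random_seq(120000)
  starts <- c(15000, 40000, 65000, 90000, 108000)
  offset <- 0L
  truth <- NULL
  for (i in seq_along(starts)) {
    cp <- mutate_sequence(q$seq, 0.04 / (2 * 3.3e-8))
    p <- plant(g, cp, starts[i] + offset)
    g <- p$genome; offset <- offset + q$length + 5L
    truth <- rbind(truth, data.frame(start = p$start, end = p$end))
  }
  # break one TSD with two mismatches just downstream of element 3
  flank_pos <- truth$end[3] + 1L
  substr(g, flank_pos, flank_pos + 1L) <-
    chartr("ACGT", "GTAC", substr(g, flank_pos, flank_pos + 1L))
  els <- call_full_length(g, q$seq, host = "Zm")
  expect_equal(length(els), 4L)
  got <- sort(vapply(els, function(e) e$genome_location$start, numeric(1)))
  expect_equal(got, truth$start[-3])
  for (e in els) {
    tsds <- c(e$tsd5, e$tsd3)
    mm <- sum(strsplit(tsds[1], "")[[1]] != strsplit(tsds[2], "")[[1]])
    expect_lte(mm, 1L)
  }
})

test_that("reverse-complement insertions are reported on the forward strand", {
  set.seed(207)
  q <- element_template(ltr_len = 300, utr5_len = 100, orf_codons = 200,
                        utr3_len = 100)
  g <- random_seq(40000)
  rc <- retroclock:::revcomp(mutate_sequence(q$seq, 0.03 / (2 * 3.3e-8)))
  p <- plant(g, rc, 18000)
  els <- call_full_length(p$genome, q$seq)
  expect_equal(length(els), 1L)
  loc <- els[[1]]$genome_location
  expect_identical(loc$strand, "-")
  expect_equal(loc$start, p$start)
  expect_equal(loc$end, p$end)
})

test_that("scanning the reverse-complemented genome mirrors coordinates", {
  set.seed(208)
  q <- element_template(ltr_len = 300, utr5_len = 100, orf_codons = 200,
                        utr3_len = 100)
  g <- random_seq(30000)
  p <- plant(g, mutate_sequence(q$seq, 0.03 / (2 * 3.3e-8)), 9000)
  fwd <- scan_genome(p$genome, q$seq)
  rev <- scan_genome(retroclock:::revcomp(p$genome), q$seq)
  L <- nchar(p$genome)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(sort(L - rev$end + 1L), sort(fwd$start))
  expect_equal(sort(L - rev$start + 1L), sort(fwd$end))
})

test_that("a nested insertion disrupts the full-length call of its target", {
  set.seed(209)
  q <- element_template(ltr_len = 300, utr5_len = 100, orf_codons = 300,
                        utr3_len = 100)
  g <- random_seq(40000)
  p <- plant(g, q$seq, 15000)
  # a younger unrelated element splits the older copy mid-ORF
  younger <- random_seq(3000)
  p2 <- plant(p$genome, younger, p$start + 1200)
  els <- call_full_length(p2$genome, q$seq)
  expect_equal(length(els), 0L)
})
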