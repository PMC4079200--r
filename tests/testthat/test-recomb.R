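test_that("self-similarity is 100% in every window", {
  set.seed(71)
  s <- random_seq(1000)
  m <- msa(c(q = s, r = s))
  prof <- similarity_profile(m, "q", "r")
  expect_true(all(prof$identity == 100))
  expect_true(all(diff(prof$centers) == prof$step))
})

test_that("a constructed 10% mismatch rate reads as 90% identity", {
  set.seed(72)
  chars <- strsplit(random_seq(1000), "")[[1]]
  alt <- chars
  idx <- seq(5, 1000, by = 10)          # exactly 20 mismatches per 200 nt
  alt[idx] <- chartr("ACGT", "GTAC", alt[idx])
  m <- msa(c(q = paste(chars, collapse = ""),
             r = paste(alt, collapse = "")))
  prof <- similarity_profile(m, "q", "r")
  expect_true(all(abs(prof$identity - 90) < 1e-9))
})

test_that("windows below 50% comparability are suppressed", {
  set.seed(73)
  s <- random_seq(600)
  gappy <- paste0(substr(s, 1, 200), paste(rep("-", 200), collapse = ""),
                  substr(s, 401, 600))
  m <- msa(c(q = s, r = gappy))
  prof <- similarity_profile(m, "q", "r")
  mid <- prof$centers > 250 & prof$centers < 350
  expect_true(all(is.na(prof$identity[mid, 1])))
  expect_true(all(!is.na(prof$identity[prof$centers < 150, 1])))
  expect_error(similarity_profile(m, "q", "r", window = 700), "exceeds")
})

test_that("window identities are symmetric under query/reference swap", {
  set.seed(74)
  anc <- random_seq(900)
  m <- msa(c(x = mutate_sequence(anc, 2e6), y = mutate_sequence(anc, 2e6)))
  p1 <- similarity_profile(m, "x", "y")
  p2 <- similarity_profile(m, "y", "x")
  expect_equal(p1$identity[, "y"], p2$identity[, "x"])
})

test_that("breakpoints are called where assignment switches persistently", {
  set.seed(75)
  anc <- random_seq(6000)
  pa <- mutate_sequence(anc, 0.05 / 3.3e-8)
  pb <- mutate_sequence(anc, 0.05 / 3.3e-8)
  rec <- recombine(pa, pb, breakpoints = 3000L)
  m <- msa(c(q = rec$seq, A = pa, B = pb))
  bc <- call_breakpoints(similarity_profile(m, "q", c("A", "B")))
  expect_length(bc$breakpoints, 1L)
  expect_lt(abs(bc$breakpoints - 3000), 2 * 20 + 1)
  expect_identical(bc$segments$label, c("A", "B"))

  # pure parent: no breakpoints
  mA <- msa(c(q = pa, A = pa, B = pb))
  bcA <- call_breakpoints(similarity_profile(mA, "q", c("A", "B")))
  expect_length(bcA$breakpoints, 0L)
})

test_that("short excursions below min_run are treated as noise", {
  # hand-built profile: A everywhere except a 2-window blip of B
  idm <- cbind(A = rep(95, 30), B = rep(80, 30))
  idm[15:16, ] <- cbind(c(80, 80), c(95, 95))
  prof <- structure(list(query = "q", refs = c("A", "B"), window = 200L,
                         step = 20L, centers = seq(101, by = 20,
                                                   length.out = 30),
                         identity = idm, n_compared = idm * 0 + 200,
                         query_coord = seq_len(1000)),
                    class = "similarity_profile")
  bc <- call_breakpoints(prof, min_run = 3)
  expect_length(bc$breakpoints, 0L)
  # margins below 2 points are ambiguous
  idm2 <- cbind(A = rep(90, 10), B = rep(89, 10))
  prof2 <- prof; prof2$identity <- idm2
  prof2$centers <- prof$centers[1:10]
  expect_error(call_breakpoints(prof2), "ambiguous")
})

test_that("subdomain typing scores parents pure and recombinants mosaic", {
  set.seed(76)
  anc <- random_seq(6500)
  pa <- mutate_sequence(anc, 0.05 / 3.3e-8)
  pb <- mutate_sequence(anc, 0.05 / 3.3e-8)
  bounds <- as.integer(seq(1, 6501, length.out = 14)[1:13])
  # breakpoint exactly at the segment 4/5 boundary
  rec <- recombine(pa, pb, breakpoints = bounds[5])
  m <- msa(c(q = rec$seq, A1 = pa, B1 = pb))
  st <- subdomain_typing(m, "A1", "B1", bounds)
  expect_identical(paste(st$q$labels, collapse = ""), "AAAABBBBBBBBB")
  stA <- subdomain_typing(m, "A1", "B1", bounds, query_ids = "A1")
  expect_identical(unique(stA$A1$labels), "A")
  stB <- subdomain_typing(m, "A1", "B1", bounds, query_ids = "B1")
  expect_identical(unique(stB$B1$labels), "B")
})

test_that("equidistant or data-poor subdomains are ambiguous", {
  set.seed(77)
  shared <- random_seq(300)          # identical in both parents: ties
  tailA <- random_seq(300)
  tailB <- mutate_sequence(tailA, 0.1 / 3.3e-8)
  pa <- paste0(shared, tailA)
  pb <- paste0(shared, tailB)
  m <- msa(c(q = pa, A = pa, B = pb))
  st <- subdomain_typing(m, "A", "B", boundaries = c(1L, 301L))
  expect_identical(st$q$labels[1], "ambiguous")   # tie in shared segment
  expect_identical(st$q$labels[2], "A")
  # gap-starved segment triggers the comparability warning
  mg <- msa(c(q = paste0(paste(rep("-", 300), collapse = ""), tailA),
              A = pa, B = pb))
  expect_warning(stg <- subdomain_typing(mg, "A", "B", c(1L, 301L),
                                         query_ids = "q"),
                 "comparable")
  expect_identical(stg$q$labels[1], "ambiguous")
})

test_that("global percent identity behaves on constructed pairs", {
  s <- random_seq(1000)
  p <- pairwise_identity(s, s)
  expect_equal(p$identity, 100)
  expect_equal(p$aligned_length, 1000L)

  s2 <- random_seq(100)
  mut <- paste0("A", substr(s2, 2, 100))
  if (substr(s2, 1, 1) == "A") mut <- paste0("C", substr(s2, 2, 100))
  p2 <- pairwise_identity(s2, mut)
  expect_equal(p2$identity, 99)
  expect_equal(p2$aligned_length, 100L)
  expect_error(pairwise_identity("", s2), "empty")
})

test_that("identity of a 0.10-divergence pair lands in the expected band", {
  set.seed(78)
  anc <- random_seq(2000)
  a <- mutate_sequence(anc, 0.05 / 3.3e-8)
  b <- mutate_sequence(anc, 0.05 / 3.3e-8)
  p <- pairwise_identity(a, b)
  expect_gt(p$identity, 89)
  expect_lt(p$identity, 92)
})
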