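test_that("zero elapsed time leaves sequences untouched", {
  s <- random_seq(500)
  expect_identical(mutate_sequence(s, 0), s)
  expect_identical(mutate_sequence(s, -1), s)
})

test_that("noncoding divergence matches the Kimura expectation", {
  L <- 10000
  years <- 0.05 / 3.3e-8
  p_exp <- k2p_expected_p(3.3e-8, years)
  for (s in 1:20) {
    set.seed(300 + s)
    anc <- random_seq(L)
    mut <- mutate_sequence(anc, years)
    ndiff <- sum(strsplit(anc, "")[[1]] != strsplit(mut, "")[[1]])
    sd3 <- 3 * sqrt(L * p_exp * (1 - p_exp))
    expect_lt(abs(ndiff - L * p_exp), sd3)
  }
})

test_that("omega = 0 ORFs accumulate no amino-acid changes", {
  set.seed(310)
  anc <- paste(sample(.sense_codons, 400, TRUE), collapse = "")
  mut <- mutate_sequence(anc, 30e6, region_map = list(ORF = c(0, nchar(anc))),
                         omega = 0)
  aa <- function(x) paste(Biostrings::GENETIC_CODE[
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))], collapse = "")
  expect_identical(aa(anc), aa(mut))
  expect_false(identical(anc, mut))   # synonymous changes did occur
})

test_that("estimated LTR divergence regresses on true age with slope 2r", {
  set.seed(320)
  r <- 3.3e-8
  t_true <- runif(100, 0.1, 2)
  k_est <- vapply(t_true, function(t) {
    ltr <- random_seq(1200)
    a <- mutate_sequence(ltr, t * 1e6)
    b <- mutate_sequence(ltr, t * 1e6)
    cs <- count_substitutions(a, b)
    retroclock:::k2p_from_pq(cs$P, cs$Q)
  }, numeric(1))
  slope <- coef(lm(k_est ~ 0 + t_true))[[1]]
  expect_lt(abs(slope - 2 * r * 1e6) / (2 * r * 1e6), 0.10)
})

test_that("insertion duplicates the 5-bp target site and grows the genome", {
  g <- "TTTTTACGTATTTTT"
  ins <- insert_element(g, "GGGGCCCC", 6)
  expect_equal(nchar(ins$genome), nchar(g) + 8 + 5)
  expect_identical(ins$tsd, "ACGTA")
  expect_identical(substr(ins$genome, ins$start - 5, ins$start - 1), "ACGTA")
  expect_identical(substr(ins$genome, ins$end + 1, ins$end + 5), "ACGTA")
  expect_identical(substr(ins$genome, ins$start, ins$end), "GGGGCCCC")
  v <- validate_tsd(ins$genome, ins$start, ins$end)
  expect_true(v$pass)
  expect_equal(v$mismatches, 0L)
})

test_that("recombination produces the specified mosaic", {
  a <- paste(rep("A", 30), collapse = "")
  b <- paste(rep("G", 30), collapse = "")
  expect_identical(recombine(a, b)$seq, a)
  r <- recombine(a, b, 11L)
  expect_identical(r$seq, paste0(substr(a, 1, 10), substr(b, 11, 30)))
  expect_identical(r$truth$parent, c("A", "B"))
  r2 <- recombine(a, b, c(11L, 21L))
  expect_identical(r2$truth$parent, c("A", "B", "A"))
  expect_error(recombine(a, b, c(21L, 11L)))
  expect_error(recombine(a, substr(b, 1, 10)))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_subfamilies = 2, transposition_rate = 0.05,
                    genome_length = 2000, seed = 17)
  s1 <- simulate_cr(cfg)
  s2 <- simulate_cr(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(vapply(s1$elements, function(e) e$seq, character(1)),
                   vapply(s2$elements, function(e) e$seq, character(1)))
  s3 <- simulate_cr(sim_config(n_subfamilies = 2, transposition_rate = 0.05,
                               genome_length = 2000, seed = 18))
  expect_false(identical(s1$genomes, s3$genomes))
})

test_that("a single host with silent transposition yields one founder element", {
  cfg <- sim_config(host_tree = "(A:10);", n_subfamilies = 1,
                    transposition_rate = 0, genome_length = 2000, seed = 5)
  sim <- simulate_cr(cfg)
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$birth_ma, 10)
  expect_identical(sim$truth$origin, "master")
})

test_that("every emitted insertion carries an intact TSD and dated LTRs", {
  cfg <- sim_config(n_subfamilies = 2, transposition_rate = 0.06,
                    genome_length = 20000, seed = 23)
  sim <- simulate_cr(cfg)
  for (i in seq_along(sim$elements)) {
    el <- sim$elements[[i]]
    loc <- el$genome_location
    v <- validate_tsd(sim$genomes[[loc$contig]], loc$start, loc$end)
    expect_true(v$pass)
    expect_equal(v$mismatches, 0L)
    expect_identical(substr(sim$genomes[[loc$contig]], loc$start, loc$end),
                     el$seq)
  }
  # young copies have near-identical LTRs: k ~ 2 r t
  young <- which(sim$truth$birth_ma < 5 & sim$truth$origin == "copy")
  for (i in young) {
    el <- sim$elements[[i]]
    cs <- count_substitutions(substr(el$seq, el$ltr5[1] + 1, el$ltr5[2]),
                              substr(el$seq, el$ltr3[1] + 1, el$ltr3[2]))
    k <- retroclock:::k2p_from_pq(cs$P, cs$Q)
    expect_lt(abs(k - 2 * 3.3e-8 * sim$truth$birth_ma[i] * 1e6), 0.03)
  }
})

test_that("cross-host divergence reflects the host split, and HT the event", {
  ht_ev <- data.frame(donor = "A", recipient = "B", subfamily = 3,
                      time_ma = 4)
  cfg <- sim_config(n_subfamilies = 3, transposition_rate = 0,
                    genome_length = 1000, ht_events = ht_ev, seed = 31)
  sim <- simulate_cr(cfg)
  expect_identical(sim$pair_truth$t_ma, c(50, 50, 4))
  pd <- element_pair_divergences(sim)
  vertical <- pd$t_ma[1:2]
  # deep divergence carries correction-model bias; wide but honest band
  expect_true(all(vertical > 30 & vertical < 75))
  expect_lt(pd$t_ma[3], 8)
  expect_true(sim$truth$ht[sim$truth$host == "B" &
                             sim$truth$subfamily == 3])
})

test_that("simulated dN/dS is below one and monotone in omega", {
  ords <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    anc <- paste(sample(.sense_codons, 500, TRUE), collapse = "")
    rm <- list(ORF = c(0, nchar(anc)))
    om <- vapply(c(0.1, 0.3, 0.7), function(w) {
      a <- mutate_sequence(anc, 20e6, region_map = rm, omega = w)
      b <- mutate_sequence(anc, 20e6, region_map = rm, omega = w)
      nei_gojobori(a, b, boot_reps = 0)$omega
    }, numeric(1))
    expect_true(all(om > 0 & om < 1))
    if (!is.unsorted(om, strictly = TRUE)) ords <- ords + 1L
  }
  expect_gte(ords, n_seeds - 1L)
})
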