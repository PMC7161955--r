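# hand-built toy locus used in several tests:
# MAC = CCCCC TA GGGGG with IES "TAAAAT" inserted at p = 5
toy_locus <- function(flank_k = 4, min_overlap = 4) {
  mac <- Biostrings::DNAStringSet(c(chr = "CCCCCTAGGGGG"))
  ann <- data.frame(ies_id = "ies1", replicon = "chr", mac_position = 5L,
                    germline_start = 5L, length = 6L, sequence = "TAAAAT",
                    stringsAsFactors = FALSE)
  germ <- Biostrings::DNAStringSet(c(chr = "CCCCCTAAAATTAGGGGG"))
  list(mac = mac, germ = germ, ann = ann,
       lib = build_junction_library(mac, germ, ann, flank_k = flank_k,
                                    min_overlap = min_overlap))
}

test_that("junction probes are the documented genome slices", {
  toy <- toy_locus()
  # insertion convention forces the germline sequence
  expect_identical(as.character(toy$germ[[1]]), "CCCCCTAAAATTAGGGGG")
  # minus probe at flank_k = 4 is MAC[1:11) = CCCCTAGGGG, sliced by hand
  expect_identical(toy$lib$probes$minus_probe, "CCCCTAGGGG")
  expect_identical(toy$lib$probes$plus_left_probe, "CCCCTAAA")
  expect_identical(toy$lib$probes$plus_right_probe, "AAATTAGG")

  bad <- toy$ann
  bad$sequence <- "GAAAAT"
  germ_bad <- Biostrings::DNAStringSet(c(chr = "CCCCCGAAAATTAGGGGG"))
  expect_error(build_junction_library(toy$mac, germ_bad, bad),
               "does not start with TA")
  expect_error(build_junction_library(toy$mac, toy$germ, toy$ann,
                                      flank_k = 2, min_overlap = 4),
               "flank_k")
})

test_that("single pairs classify by junction-probe containment", {
  toy <- toy_locus()
  minus_core <- toy$lib$windows$seq[toy$lib$windows$probe == "minus"]
  plus_core <- toy$lib$windows$seq[toy$lib$windows$probe == "plus_left"]

  res <- classify_read_pair(minus_core, "TTTTTTTTTT", toy$lib)
  expect_identical(res$label, "IES-")
  expect_identical(res$ies_id, "ies1")

  # reverse complement of a probe window is an equivalent match
  res_rc <- classify_read_pair(.rc(plus_core), "TTTTTTTTTT", toy$lib)
  expect_identical(res_rc$label, "IES+")

  # random sequence absent from both genomes
  expect_identical(classify_read_pair("TTGTTGTTGTTG", "TGTTGTTGT",
                                      toy$lib)$label, "unassigned")
  expect_identical(classify_read_pair("", "", toy$lib)$label, "unassigned")

  # both signs for the same IES in one pair: ambiguous, votes discarded
  chimera <- paste0(minus_core, plus_core)
  resc <- classify_read_pair(chimera, "TTTTTTTTTT", toy$lib)
  expect_identical(resc$label, "ambiguous")
  expect_identical(nrow(resc$votes), 0L)
})

test_that("classification equals the brute-force substring-scan oracle", {
  for (seed in c(101, 202, 303)) {
    g <- generate_genome_pair(tiny_config(seed))
    tr <- simulation_truth(assign_retention(g$annotations,
                                            model = "uniform", r = 0.4), 0.6)
    rs <- simulate_read_pairs(g, tr, coverage = 25, rng_seed = seed + 1)
    lib <- build_junction_library(g$mac, g$germline, g$annotations,
                                  flank_k = 50)
    got <- count_and_score(rs, lib)
    want <- brute_counts(rs$read1, rs$read2, lib)
    expect_identical(got$ies_plus, want$ies_plus)
    expect_identical(got$ies_minus, want$ies_minus)
    expect_identical(got$ambiguous, want$ambiguous)
  }
})

test_that("retention scores are count ratios with the documented edge cases", {
  expect_equal(compute_irs(3, 1), 0.75)
  expect_equal(compute_irs(0, 10), 0)
  expect_equal(compute_irs(10, 0), 1)
  expect_true(is.na(compute_irs(0, 0)))
  expect_error(compute_irs(-1, 2), "non-negative")
  # monotone non-decreasing in ies_plus for fixed ies_minus
  irs <- compute_irs(0:50, 7)
  expect_true(all(diff(irs) >= 0))
  expect_true(all(irs >= 0 & irs <= 1))
})

test_that("expected apparent IRS reduces to rho * r and inverts exactly", {
  expect_equal(expected_apparent_irs(0, 0.3), 0)
  expect_equal(expected_apparent_irs(1, 1), 1)
  # dilution by old-MAC DNA: full retention at rho = 0.15 scores 0.15
  expect_equal(expected_apparent_irs(1, 0.15), 0.15)
  expect_equal(expected_apparent_irs(0.4, 0.5), 0.2)
  expect_error(expected_apparent_irs(1.2, 0.5), "\\[0, 1\\]")
  expect_error(expected_apparent_irs(0.5, -0.1), "\\[0, 1\\]")

  # estimator round trip, with and without the catchment correction
  r <- seq(0, 1, by = 0.05)
  expect_equal(estimate_retention(expected_apparent_irs(r, 0.5), 0.5), r)
  k <- vote_catchment(28, 100, 300)$ratio
  irs <- expected_apparent_irs(r, 0.5, k)
  expect_equal(estimate_retention(irs, 0.5, rep(28, length(r)), 100, 300), r)
})

test_that("vote catchments match hand enumeration and the template oracle", {
  # tiny geometry worked out by hand: reads 10 nt, insert 20, m = 2, L = 6.
  # IES- window [-2, 4): mate 1 starts [-6, -2], mate 2 starts [-16, -12],
  # 10 positions. IES+ windows [-2, 2) and [4, 8): mate 1 union [-8, 4],
  # mate 2 union [-18, -6], overlapping on [-8, -6]: 23 positions.
  cc <- vote_catchment(6, read_length = 10, mean_insert = 20, min_overlap = 2)
  expect_identical(c(cc$c_plus, cc$c_minus), c(23L, 10L))

  # against the exhaustive fragment-position oracle on a real template
  g <- one_ies_genome(77)
  lib <- build_junction_library(g$mac, g$germline, g$annotations,
                                flank_k = 100)
  oracle <- enum_catchment(g, lib, read_length = 100, insert = 300)
  cc2 <- vote_catchment(g$annotations$length, 100, 300)
  expect_identical(cc2$c_plus, oracle$c_plus)
  expect_identical(cc2$c_minus, oracle$c_minus)
})

test_that("mean scores track the fragment-enumeration oracle expectation", {
  g <- one_ies_genome(55)
  lib <- build_junction_library(g$mac, g$germline, g$annotations,
                                flank_k = 100)
  tr <- simulation_truth(setNames(0.5, g$annotations$ies_id), rho = 1)
  rs <- simulate_read_pairs(g, tr, coverage = 200, rng_seed = 6)
  sc <- count_and_score(rs, lib)
  cc <- enum_catchment(g, lib, read_length = 100, insert = 300)
  expect_lt(abs(sc$irs - enum_expected_irs(0.5, 1, cc$c_plus, cc$c_minus)),
            0.03 + 3 * sqrt(0.25 / (sc$ies_plus + sc$ies_minus)))
})

test_that("significance calls come from a one-sided exact test with BH", {
  rec <- function(plus, minus) {
    data.frame(ies_id = paste0("i", seq_along(plus)),
               replicon = "chr", position = seq_along(plus),
               ies_plus = plus, ies_minus = minus, ambiguous = 0L,
               irs = compute_irs(plus, minus), stringsAsFactors = FALSE)
  }
  # overwhelming retention vs clean control
  tt <- test_retention(rec(100, 0), rec(0, 100))
  expect_true(tt$significant)
  expect_lt(tt$p_value, 1e-50)
  # cross-check against the hypergeometric tail
  expect_equal(tt$p_value, phyper(100 - 1, 100, 100, 100, lower.tail = FALSE))

  # identical counts cannot be significant one-sided
  tt2 <- test_retention(rec(c(5, 8), c(5, 4)), rec(c(5, 8), c(5, 4)))
  expect_true(all(!tt2$significant))
  expect_true(all(tt2$p_value >= 0.5))

  # coverage gate: too few reads in either condition leaves the IES untested
  tt3 <- test_retention(rec(1, 0), rec(0, 1), min_reads = 10)
  expect_false(tt3$tested)
  expect_true(is.na(tt3$significant))

  a <- rec(c(10, 2), c(0, 9))
  b <- rec(c(0, 1), c(10, 10))
  b2 <- b
  b2$ies_id <- c("i1", "iX")
  expect_error(test_retention(a, b2), "different IES sets")

  # BH adjustment across tested IESs only
  tt4 <- test_retention(rec(c(20, 12, 1), c(0, 8, 0)),
                        rec(c(0, 10, 0), c(20, 10, 1)))
  expect_equal(tt4$q_value[tt4$tested],
               p.adjust(tt4$p_value[tt4$tested], "BH"))
  expect_true(is.na(tt4$q_value[3]))
})
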