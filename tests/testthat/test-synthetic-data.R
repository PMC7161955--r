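test_that("IES lengths follow the configured size-peak mixture", {
  # degenerate mixture: all weight on the first peak
  l1 <- sample_ies_lengths(100, c(1), rng_seed = 1)
  expect_true(all(l1 >= 26 & l1 <= 30))

  expect_identical(sample_ies_lengths(0, c(0.5, 0.5), rng_seed = 1),
                   integer(0))

  # first-peak fraction inside the exact binomial 99% interval around 0.7
  l3 <- sample_ies_lengths(10000, c(0.7, 0.2, 0.1), rng_seed = 42)
  n1 <- sum(l3 <= 30)
  expect_gte(n1, qbinom(0.005, 10000, 0.7))
  expect_lte(n1, qbinom(0.995, 10000, 0.7))
  # second bin advances by the 10 bp period
  expect_true(all(l3[l3 > 30 & l3 < 46] >= 36 & l3[l3 > 30 & l3 < 46] <= 40))

  expect_error(sample_ies_lengths(-1, c(1)), "non-negative")
  expect_error(sample_ies_lengths(10, c(0.5, 0.4)), "sum to 1")
  expect_identical(sample_ies_lengths(50, c(1), rng_seed = 7),
                   sample_ies_lengths(50, c(1), rng_seed = 7))
})

test_that("genome pairs satisfy the TA insertion convention and round-trip", {
  g <- generate_genome_pair(tiny_config(5, n_ies = 1))
  a <- g$annotations
  expect_equal(sum(Biostrings::width(g$germline)),
               sum(Biostrings::width(g$mac)) + a$length)
  mac <- as.character(g$mac[[1]])
  expect_identical(substr(mac, a$mac_position + 1, a$mac_position + 2), "TA")
  expect_identical(substr(a$sequence, 1, 2), "TA")

  # excising every annotated IES reproduces the MAC byte-exactly, many seeds
  for (seed in 1:100) {
    gp <- generate_genome_pair(tiny_config(seed))
    expect_identical(as.character(excise_ies(gp$germline, gp$annotations)),
                     as.character(gp$mac))
  }
})

test_that("clustered placement produces IES-dense neighborhoods", {
  cfg <- simulation_config(n_replicons = 1, replicon_length = 30000,
                           n_ies = 20, cluster_fraction = 0.5,
                           dense_region_count = 2, dense_region_span = 2000,
                           read_length = 50, mean_insert = 140, rng_seed = 3)
  g <- generate_genome_pair(cfg)
  expect_gte(max(brute_density(g$annotations, 1000)), 3)
  expect_true(any(g$annotations$in_dense_region))
})

test_that("infeasible packing is a generation error", {
  cfg <- simulation_config(n_replicons = 1, replicon_length = 2000,
                           n_ies = 50, dense_region_count = 0,
                           read_length = 50, mean_insert = 140, rng_seed = 1)
  expect_error(generate_genome_pair(cfg), "infeasible packing")
})

test_that("retention models assign the documented probabilities", {
  g <- generate_genome_pair(tiny_config(9, n_ies = 8))
  d <- neighbor_density(g$annotations)
  expect_true(all(assign_retention(g$annotations, model = "all_retained") == 1))
  expect_true(all(assign_retention(g$annotations, model = "none_retained") == 0))
  expect_true(all(assign_retention(g$annotations, model = "uniform",
                                   r = 0.3) == 0.3))
  expect_error(assign_retention(g$annotations, model = "no_such_model"))
  expect_error(assign_retention(g$annotations, model = "feature_logistic"),
               "densities")

  # logistic model: direct evaluation; short+dense must beat long+isolated
  r <- assign_retention(g$annotations, d, model = "feature_logistic",
                        b0 = -4, b_len = 3, b_dens = 0.5)
  expect_equal(unname(r),
               plogis(-4 + 3 * (g$annotations$length <= 30) +
                        0.5 * unname(d[g$annotations$ies_id])))
  short_dense <- g$annotations$length <= 30 & d[g$annotations$ies_id] >= 1
  long_iso <- g$annotations$length > 30 & d[g$annotations$ies_id] == 0
  if (any(short_dense) && any(long_iso))
    expect_gt(mean(r[short_dense]), mean(r[long_iso]))
})

test_that("read simulation respects the mixture and the coverage target", {
  g <- generate_genome_pair(tiny_config(11, replicon_length = 10000,
                                        n_ies = 8))
  ann <- g$annotations

  # rho = 0: everything is old-MAC material
  tr0 <- simulation_truth(assign_retention(ann, model = "uniform", r = 0.5),
                          rho = 0)
  rs0 <- simulate_read_pairs(g, tr0, coverage = 20, rng_seed = 2)
  expect_true(all(rs0$provenance == "old_mac"))

  # rho = 1, all r = 1: no excised template exists, so no read matches any
  # excised-junction probe
  tr1 <- simulation_truth(assign_retention(ann, model = "all_retained"),
                          rho = 1)
  rs1 <- simulate_read_pairs(g, tr1, coverage = 20, rng_seed = 2)
  lib <- build_junction_library(g$mac, g$germline, ann, flank_k = 50)
  minus <- lib$windows[lib$windows$call == "IES-", , drop = FALSE]
  hits <- vapply(minus$seq, function(w)
    any(grepl(w, as.character(rs1$read1), fixed = TRUE)) ||
      any(grepl(.rc(w), as.character(rs1$read1), fixed = TRUE)) ||
      any(grepl(w, as.character(rs1$read2), fixed = TRUE)) ||
      any(grepl(.rc(w), as.character(rs1$read2), fixed = TRUE)),
    logical(1))
  expect_false(any(hits))

  # empirical mean depth within 10% of the 50X target on a 10 kb genome
  tr <- simulation_truth(assign_retention(ann, model = "uniform", r = 0.2),
                         rho = 0.5)
  rs <- simulate_read_pairs(g, tr, coverage = 50, read_length = 100,
                            mean_insert = 300, rng_seed = 5)
  depth <- rs$n_fragments * 2 * 100 / sum(Biostrings::width(g$mac))
  expect_lt(abs(depth - 50) / 50, 0.1)
})

test_that("identical config and seed reproduce genomes and reads exactly", {
  cfg <- tiny_config(21)
  g1 <- generate_genome_pair(cfg)
  g2 <- generate_genome_pair(cfg)
  expect_identical(as.character(g1$germline), as.character(g2$germline))
  expect_identical(g1$annotations, g2$annotations)

  tr <- simulation_truth(assign_retention(g1$annotations,
                                          model = "uniform", r = 0.5), 0.5)
  r1 <- simulate_read_pairs(g1, tr, coverage = 10, rng_seed = 4)
  r2 <- simulate_read_pairs(g2, tr, coverage = 10, rng_seed = 4)
  expect_identical(as.character(r1$read1), as.character(r2$read1))
  expect_identical(as.character(r1$read2), as.character(r2$read2))
  expect_identical(r1$provenance, r2$provenance)

  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  dir.create(d1, showWarnings = FALSE)
  dir.create(d2, showWarnings = FALSE)
  write_genome_fasta(g1$mac, file.path(d1, "mac.fasta"))
  write_genome_fasta(g2$mac, file.path(d2, "mac.fasta"))
  expect_identical(readLines(file.path(d1, "mac.fasta")),
                   readLines(file.path(d2, "mac.fasta")))
})

test_that("provenance never tags an old-MAC fragment as retained and the
           junction mixture matches the enumeration oracle", {
  g <- one_ies_genome(31)
  ann <- g$annotations
  lib <- build_junction_library(g$mac, g$germline, ann, flank_k = 100)
  r <- 0.6
  rho <- 0.7
  tr <- simulation_truth(setNames(r, ann$ies_id), rho)
  rs <- simulate_read_pairs(g, tr, coverage = 400, rng_seed = 8)

  res <- classify_read_pairs(rs$read1, rs$read2, lib)
  voting <- res$votes$pair
  prov <- rs$provenance[voting]
  # all IES+ votes come from new_retained templates, IES- votes never do
  expect_true(all(prov[res$votes$call == "IES+"] == "new_retained"))
  expect_true(all(prov[res$votes$call == "IES-"] != "new_retained"))

  cc <- enum_catchment(g, lib, read_length = 100, insert = 300)
  expected_fraction <- r * rho * cc$c_plus /
    (r * rho * cc$c_plus + (1 - r * rho) * cc$c_minus)
  observed <- mean(res$votes$call == "IES+")
  n <- nrow(res$votes)
  ci <- qbinom(c(0.005, 0.995), n, expected_fraction) / n
  expect_gte(observed, ci[1])
  expect_lte(observed, ci[2])
})

test_that("planted logistic effects surface in the true-retained set", {
  cfg <- simulation_config(n_replicons = 1, replicon_length = 60000,
                           n_ies = 60, cluster_fraction = 0.4,
                           dense_region_count = 3, dense_region_span = 2000,
                           read_length = 50, mean_insert = 140, rng_seed = 13)
  g <- generate_genome_pair(cfg)
  d <- neighbor_density(g$annotations)
  r <- assign_retention(g$annotations, d, model = "feature_logistic",
                        b0 = -4, b_len = 3, b_dens = 0.5)
  retained <- names(r)[r > 0.5]
  expect_gt(length(retained), 0)
  ann <- g$annotations
  in_ret <- ann$ies_id %in% retained
  expect_gt(mean(ann$length[in_ret] <= 30), mean(ann$length <= 30))
  expect_gt(mean(d[ann$ies_id[in_ret]]), mean(d))
})
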