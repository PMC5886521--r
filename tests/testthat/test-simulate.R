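test_that("accepted-set sampling is uniform over the product space", {
  p <- compile_pattern("paper-union")
  withr::with_seed(1, {
    draws <- sample_accepted_site(p, 2000)
  })
  m <- match_window(draws, p)
  expect_true(all(m$matched))
  # 6 of the 7 arm-2 variants carry a mismatch under uniform enumeration
  frac_mm <- mean(m$arm_mismatch_position > 0)
  expect_equal(frac_mm, 6 / 7, tolerance = 0.03)

  withr::with_seed(99, a <- sample_accepted_site(p, 20))
  withr::with_seed(99, b <- sample_accepted_site(p, 20))
  expect_identical(a, b)
})

test_that("generated genomes are deterministic and carry a complete truth", {
  p <- compile_pattern("paper-union")
  cfg <- generator_config(seed = 11, genome_length = 20000, n_sites = 10)
  g1 <- gen_genome(cfg, p)
  g2 <- gen_genome(cfg, p)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$truth, g2$truth)

  # every recorded site really matches, in its recorded orientation
  t <- g1$truth$planted_sites
  oriented <- orient_site(t)
  expect_true(all(match_window(oriented, p)$matched))

  # G/C-free background cannot create accidental sites: truth = planted
  pure <- gen_genome(generator_config(seed = 11, genome_length = 20000,
                                      n_sites = 10, at_fraction = 1.0), p)
  expect_true(all(pure$truth$planted_sites$planted))
  expect_equal(nrow(pure$truth$planted_sites), 10L)

  expect_error(gen_genome(generator_config(seed = 1, genome_length = 400,
                                           n_sites = 10), p),
               class = "rex_config_error")
})

test_that("deny-listed products exclude their sites from the expected regulon", {
  p <- compile_pattern("paper-union")
  g <- gen_genome(generator_config(seed = 13, genome_length = 40000,
                                   n_sites = 8, frac_hypothetical = 1.0), p)
  expect_equal(nrow(g$truth$expected_regulon), 0L)

  far <- gen_genome(generator_config(seed = 13, genome_length = 40000,
                                     n_sites = 8, frac_near_gene = 0), p)
  # all genes are farther than 200 bp, so nothing passes the distance filter
  expect_equal(nrow(far$truth$expected_regulon), 0L)
})

test_that("GFF3 output is standard and empty feature lists are legal", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "empty.gff3")
  gen_gff(tibble::tibble(contig = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         locus_tag = character(0), gene_name = character(0),
                         product = character(0)), out)
  expect_equal(readLines(out), "##gff-version 3")

  dup <- tibble::tibble(contig = "c", start = c(0L, 100L), end = c(50L, 150L),
                        strand = "+", locus_tag = c("A", "A"),
                        gene_name = NA_character_, product = "x")
  expect_error(gen_gff(dup, file.path(dir, "dup.gff3")),
               class = "rex_input_error")
})

test_that("OD curve generation matches its logistic model", {
  g <- gen_od_curves(c(a = 0.2), K = 0.5, od0 = 0.01, dt = 0.5, t_max = 10,
                     noise_sd = 0, seed = 1)
  t <- g$od_table$time_h
  manual <- 0.5 * 0.01 * exp(0.2 * t) / (0.5 + 0.01 * (exp(0.2 * t) - 1))
  expect_equal(g$od_table$od600, manual)

  flat <- gen_od_curves(c(a = 0), t_max = 5, seed = 1)
  expect_equal(diff(range(flat$od_table$od600)), 0)

  r1 <- gen_od_curves(c(a = 0.2), noise_sd = 0.05, seed = 4, t_max = 5)
  r2 <- gen_od_curves(c(a = 0.2), noise_sd = 0.05, seed = 4, t_max = 5)
  expect_identical(r1, r2)
  expect_error(gen_od_curves(c(a = 0.2), K = 0), class = "rex_config_error")
  expect_error(gen_od_curves(c(0.2)), class = "rex_config_error")
})

test_that("breakpoint tables carry labels computed by the strict rule", {
  bt <- gen_breakpoint_table(n = 200, pass_fraction = 0.5, seed = 3)
  manual <- bt$breakpoints$read_count >= 10 &
    bt$breakpoints$frac_not_perfectly_matched >= 0.20
  expect_identical(bt$pass_label, manual)
  # boundary rows are present and labeled by rule
  expect_true(any(bt$breakpoints$read_count == 10 &
                    bt$breakpoints$frac_not_perfectly_matched == 0.20 &
                    bt$pass_label))
  expect_true(any(bt$breakpoints$read_count == 9 & !bt$pass_label))

  none <- gen_breakpoint_table(n = 100, pass_fraction = 0, seed = 3)
  expect_equal(nrow(filter_breakpoints(none$breakpoints)), 0L)
})

test_that("fermentation tables invert the yield calculation", {
  f <- gen_fermentation_table(c(wt = 40, rex = 91, adp = 56))
  y <- percent_theoretical_yield(f$table)
  expect_equal(y$percent_theoretical, c(40, 91, 56), tolerance = 0.005)

  zero <- gen_fermentation_table(c(s = 0))
  expect_equal(zero$table$ethanol, 0)
  full <- gen_fermentation_table(c(s = 100), consumed = 5)
  expect_equal(full$table$ethanol, 5 * theoretical_yield_coeff("cellobiose"))

  expect_error(gen_fermentation_table(c(s = 151)), class = "rex_config_error")
})

test_that("qPCR generation is exact at zero noise and reproducible", {
  q0 <- gen_qpcr(c(adhE = 10, adhA = 2), noise_sd = 0, seed = 1)
  curve <- fit_standard_curve(q0$standards)
  out <- quantify_and_normalize(q0$samples, curve)
  expect_equal(out$ratio[out$target == "adhE"], 10, tolerance = 1e-9)
  expect_equal(out$ratio[out$target == "adhA"], 2, tolerance = 1e-9)
  expect_equal(out$ratio[out$target == "recA"], 1)

  a <- gen_qpcr(c(adhE = 10), noise_sd = 0.2, seed = 8)
  b <- gen_qpcr(c(adhE = 10), noise_sd = 0.2, seed = 8)
  expect_identical(a, b)
})
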