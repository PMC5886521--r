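test_that("background subtraction removes exact-key matches only", {
  sample <- tibble::tibble(
    contig = "chr", pos = c(100L, 200L, 300L),
    ref = c("C", "T", "G"), alt = c("A", "C", "T")
  )
  control <- tibble::tibble(
    contig = "chr", pos = c(200L, 300L),
    ref = c("T", "G"), alt = c("C", "A")  # pos 300 has a different alt
  )
  out <- subtract_background(sample, control)
  expect_equal(out$pos, c(100L, 300L))
  expect_equal(subtract_background(sample, control[0, ]), sample)
})

test_that("breakpoint filtering is strict below both thresholds", {
  bp <- tibble::tibble(
    contig = "chr", pos = 1:4 * 100L, side = "left",
    read_count = c(9L, 10L, 50L, 10L),
    frac_not_perfectly_matched = c(0.5, 0.20, 0.19, 0.20),
    unaligned_seq = strrep("A", 20)
  )
  kept <- filter_breakpoints(bp)
  expect_equal(kept$pos, c(200L, 400L))  # boundary (10, 0.20) retained
  expect_error(filter_breakpoints(bp, min_reads = -1),
               class = "rex_config_error")
})

make_bp <- function(pos, side, seq, contig = "chr") {
  tibble::tibble(contig = contig, pos = pos, side = side,
                 read_count = 30L, frac_not_perfectly_matched = 0.5,
                 unaligned_seq = seq)
}

test_that("breakpoint pairing requires span and shared sequence", {
  shared <- "ACGTACGTTGCAACGTTGCA"  # 20 bp
  lefts <- make_bp(1000L, "left", paste0("TTTTT", shared, "AAAAA"))
  rights <- make_bp(1300L, "right", paste0("GG", shared, "CC"))
  calls <- pair_breakpoints(lefts, rights)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$span, 300L)
  expect_equal(calls$evidence_seq, shared)

  # no partner within range
  expect_equal(nrow(suppressMessages(
    pair_breakpoints(lefts, make_bp(1e6L, "right", shared)))), 0L)
  # shared sequence too short
  expect_equal(nrow(suppressMessages(
    pair_breakpoints(lefts, make_bp(1300L, "right", substr(shared, 1, 10))))),
    0L)
  # reverse-complement overlap also counts
  rc <- pair_breakpoints(lefts, make_bp(1300L, "right",
                                        reverse_complement(shared)))
  expect_equal(nrow(rc), 1L)
})

test_that("equidistant pairing ties break to the lower-coordinate right", {
  shared <- "ACGTACGTTGCAACGTTGCA"
  lefts <- make_bp(1000L, "left", shared)
  rights <- make_bp(c(700L, 1300L), "right", shared)
  calls <- suppressMessages(pair_breakpoints(lefts, rights))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$right_pos, 700L)
})

test_that("pairing conserves breakpoints and evidence appears in both partners", {
  withr::with_seed(21, {
    core <- vapply(1:6, function(i) {
      paste0(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
    }, "")
    lefts <- make_bp(seq(1000L, by = 2000L, length.out = 6), "left",
                     paste0("TT", core))
    rights <- make_bp(seq(1400L, by = 2000L, length.out = 6), "right",
                      ifelse(seq_along(core) %% 2 == 0,
                             reverse_complement(core), core))
  })
  calls <- suppressMessages(pair_breakpoints(lefts, rights))
  expect_lte(nrow(calls), min(nrow(lefts), nrow(rights)))
  for (i in seq_len(nrow(calls))) {
    l <- lefts$unaligned_seq[lefts$pos == calls$left_pos[i]]
    r <- rights$unaligned_seq[rights$pos == calls$right_pos[i]]
    ev <- calls$evidence_seq[i]
    expect_true(grepl(ev, l, fixed = TRUE) ||
                  grepl(reverse_complement(ev), l, fixed = TRUE))
    expect_true(grepl(ev, r, fixed = TRUE) ||
                  grepl(reverse_complement(ev), r, fixed = TRUE))
  }
  expect_error(
    pair_breakpoints(make_bp(1L, "left", strrep("A", 80)), rights),
    class = "rex_input_error")
})

# A synthetic CDS with known residues: poly-Lys (AAA) with Glu at 454 and
# Thr at 597; 700 codons, stop-free before the variants.
demo_cds <- local({
  s <- strrep("AAA", 700)
  substr(s, 454 * 3 - 2, 454 * 3) <- "GAA"
  substr(s, 597 * 3 - 2, 597 * 3) <- "ACA"
  s
})
demo_gene <- tibble::tibble(contig = "chr", start = 1000L,
                            end = 1000L + nchar(demo_cds), strand = "+",
                            locus_tag = "Tsac_demo")

test_that("coding-effect nomenclature covers the published mutation styles", {
  # missense: ACA -> AAA at codon 597 (C -> A in the genome)
  mis <- annotate_coding_effect(
    tibble::tibble(pos = 1000L + 597L * 3L - 1L, ref = "C", alt = "A",
                   type = "SNV"), demo_gene, demo_cds)
  expect_equal(mis$kind, "missense")
  expect_equal(mis$description, "Thr597Lys")

  # nonsense: GAA -> TAA at codon 454
  non <- annotate_coding_effect(
    tibble::tibble(pos = 1000L + 454L * 3L - 2L, ref = "G", alt = "T",
                   type = "SNV"), demo_gene, demo_cds)
  expect_equal(non$kind, "nonsense")
  expect_equal(non$description, "Glu454*")

  # frameshift: single-base deletion in codon 290
  fs <- annotate_coding_effect(
    tibble::tibble(pos = 1000L + 290L * 3L - 1L, ref = "A", alt = "-",
                   type = "DEL"), demo_gene, demo_cds)
  expect_equal(fs$kind, "frameshift")
  expect_equal(fs$description, "Lys290fs")

  # synonymous third-position change: AAA -> AAG
  syn <- annotate_coding_effect(
    tibble::tibble(pos = 1000L + 3L * 3L, ref = "A", alt = "G",
                   type = "SNV"), demo_gene, demo_cds)
  expect_equal(syn$kind, "synonymous")
  expect_equal(syn$description, "Lys3Lys")

  # upstream variant reports a signed offset
  up <- annotate_coding_effect(
    tibble::tibble(pos = 817L, ref = "C", alt = "T", type = "SNV"),
    demo_gene, demo_cds)
  expect_equal(up$kind, "upstream")
  expect_equal(up$offset, -184L)
  expect_match(up$description, "184 bp upstream")
})

test_that("coding effects are strand-aware and validated", {
  # same CDS on the minus strand: genomic C -> A equals coding G -> T
  minus_gene <- tibble::tibble(contig = "chr", start = 1000L,
                               end = 1000L + nchar(demo_cds), strand = "-",
                               locus_tag = "Tsac_minus")
  # coding position of codon 454 base 1 maps to genomic end - cpos + 1
  gpos <- minus_gene$end - (454L * 3L - 2L) + 1L
  non <- annotate_coding_effect(
    tibble::tibble(pos = gpos, ref = "C", alt = "A", type = "SNV"),
    minus_gene, demo_cds)
  expect_equal(non$description, "Glu454*")

  # allele disagreeing with the CDS is an annotation mismatch
  expect_error(annotate_coding_effect(
    tibble::tibble(pos = 1001L, ref = "G", alt = "T", type = "SNV"),
    demo_gene, demo_cds), regexp = "mismatch", class = "rex_input_error")

  # variant far upstream is out of contract
  expect_error(annotate_coding_effect(
    tibble::tibble(pos = 100L, ref = "C", alt = "T", type = "SNV"),
    demo_gene, demo_cds), class = "rex_input_error")

  # internal stop before the variant flags a broken annotation
  broken <- demo_cds
  substr(broken, 10, 12) <- "TAA"
  expect_error(annotate_coding_effect(
    tibble::tibble(pos = 1000L + 597L * 3L - 1L, ref = "C", alt = "A",
                   type = "SNV"), demo_gene, broken),
    regexp = "internal stop", class = "rex_input_error")
})

test_that("described mutations round-trip through re-translation", {
  translate_cds <- function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste0(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
  }
  eff <- annotate_coding_effect(
    tibble::tibble(pos = 1000L + 597L * 3L - 1L, ref = "C", alt = "A",
                   type = "SNV"), demo_gene, demo_cds)
  parsed <- parse_coding_description(eff$description)
  mutated <- demo_cds
  substr(mutated, 597L * 3L - 1L, 597L * 3L - 1L) <- "A"
  prot <- translate_cds(mutated)
  expect_equal(substr(prot, parsed$residue, parsed$residue), "K")
  expect_equal(parsed$ref_aa, "Thr")
  expect_equal(parsed$alt, "Lys")
  expect_equal(parse_coding_description("Glu454*")$alt, "*")
  expect_equal(parse_coding_description("Lys290fs")$alt, "fs")
  expect_error(parse_coding_description("not-a-mutation"),
               class = "rex_input_error")
})

test_that("variants load from TSV and minimal VCF", {
  dir <- withr::local_tempdir()

  tsv <- file.path(dir, "vars.tsv")
  readr::write_tsv(tibble::tibble(
    contig = "chr", pos = c(10L, 20L), ref = c("C", "A"), alt = c("A", "AT")
  ), tsv)
  vt <- read_variants(tsv)
  expect_equal(vt$type, c("SNV", "INS"))

  vcf <- file.path(dir, "vars.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr\t449017\t.\tC\tA\t50\tPASS\tAF=0.57",
    "chr\t2539210\t.\tAT\tA\t50\tPASS\tAF=0.99"
  ), vcf)
  vv <- read_variants(vcf)
  expect_equal(vv$pos, c(449017L, 2539210L))
  expect_equal(vv$supporting_fraction, c(0.57, 0.99))
  expect_equal(vv$type, c("SNV", "DEL"))
})
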