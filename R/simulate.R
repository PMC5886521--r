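# Seeded, truth-labeled synthetic inputs for every pipeline stage. The
# generators implement the stated rules directly (arithmetic on planted
# coordinates, inverse yield/qPCR models); the single exception is the final
# re-scan in gen_genome(), which uses the scanner itself so that accidental
# background matches are part of the recorded truth.

#' Generator configuration for synthetic genomes
#'
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   genome byte for byte.
#' @param genome_length Contig length in bp.
#' @param at_fraction Background A+T fraction (default 0.65, a
#'   Thermoanaerobacterium-like AT-rich genome).
#' @param n_sites Number of planted operator windows (half per strand).
#' @param frac_near_gene Fraction of sites given an annotated gene within
#'   200 bp downstream; the rest get a gene 201-320 bp away, so they are
#'   annotated but excluded by the distance filter.
#' @param frac_hypothetical Fraction of the near genes labeled
#'   "hypothetical protein", exercising the annotation filter.
#' @param contig Contig identifier.
#' @return A list of class `rex_gen_config`.
#' @export
generator_config <- function(seed, genome_length = 100000, at_fraction = 0.65,
                             n_sites = 20, frac_near_gene = 1.0,
                             frac_hypothetical = 0, contig = "synth_contig_1") {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(genome_length, "genome_length", min = 18)
  if (at_fraction < 0 || at_fraction > 1) {
    abort("`at_fraction` must be in [0, 1].", class = "rex_config_error")
  }
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         at_fraction = at_fraction, n_sites = as.integer(n_sites),
         frac_near_gene = frac_near_gene,
         frac_hypothetical = frac_hypothetical, contig = contig),
    class = "rex_gen_config"
  )
}

#' Draw windows uniformly from a pattern's accepted set
#'
#' Constructive sampling of the product space arm-1 x admissible spacer x
#' admissible arm-2 variant, with component weights chosen so the draw is
#' uniform over the full accepted set (so under the union pattern about 6 of
#' 7 draws carry an arm mismatch). Uses the current RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @param p A [compile_pattern()] object.
#' @param n Number of windows to draw.
#' @return Character vector of `n` accepted windows.
#' @export
sample_accepted_site <- function(p, n = 1) {
  stopifnot(inherits(p, "rex_pattern"))
  vapply(seq_len(n), function(i) {
    arm1 <- paste0(vapply(p$arm_template,
                          function(s) sample_one(ARM_ALPHABET[[s]]), ""),
                   collapse = "")
    n0 <- 2^p$spacer_len
    n1 <- p$spacer_len * 2 * 2^(p$spacer_len - 1)
    gc_here <- p$max_spacer_gc >= 1 && runif(1) < n1 / (n0 + n1)
    spacer <- vapply(seq_len(p$spacer_len),
                     function(j) sample_one(c("A", "T")), "")
    if (gc_here) {
      spacer[sample.int(p$spacer_len, 1)] <- sample_one(c("C", "G"))
    }
    arm2 <- expected_arm2(arm1)
    n_var <- 1L + if (p$max_arm_mismatches > 0) {
      3L * length(p$allowed_arm2_mismatch_positions)
    } else 0L
    v <- sample.int(n_var, 1)
    if (v > 1L) {
      pos <- p$allowed_arm2_mismatch_positions[ceiling((v - 1L) / 3)]
      alt <- setdiff(DNA_BASES, substr(arm2, pos, pos))[(v - 2L) %% 3L + 1L]
      substr(arm2, pos, pos) <- alt
    }
    paste0(arm1, paste0(spacer, collapse = ""), arm2)
  }, "")
}

sample_one <- function(x) x[sample.int(length(x), 1)]

#' Generate an AT-rich genome with planted operator sites and genes
#'
#' Draws an i.i.d. background at the configured A+T fraction, plants
#' `n_sites` accepted windows (drawn by [sample_accepted_site()], alternating
#' strands) at evenly spaced, non-overlapping loci, and places a gene
#' downstream of each site on the site's strand. After planting, the whole
#' contig is re-scanned with the pattern and any accidental background
#' matches are appended to the recorded truth, so the truth table is complete
#' by construction.
#'
#' @param cfg A [generator_config()].
#' @param p A [compile_pattern()] object.
#' @param fasta_path Optional path; when given the genome is written there as
#'   FASTA.
#' @return List with `sequence` (contig string), `contig`, and `truth`: a
#'   list of `planted_sites` (every matching window: contig, start, strand,
#'   forward_seq, planted flag), `genes` (feature tibble) and
#'   `expected_regulon` (locus_tag, site start, distance -- the rows the
#'   annotate-and-filter stage must report).
#' @export
gen_genome <- function(cfg, p, fasta_path = NULL) {
  stopifnot(inherits(cfg, "rex_gen_config"), inherits(p, "rex_pattern"))
  if (cfg$genome_length < cfg$n_sites * 50L) {
    abort("genome_length must be at least 50 bp per planted site.",
          class = "rex_config_error")
  }
  set.seed(cfg$seed)
  L <- cfg$genome_length
  n <- cfg$n_sites
  len <- window_length(p)
  slot <- L %/% max(n, 1L)
  if (slot < len + 40L) {
    abort("infeasible packing: sites would overlap; enlarge the genome.",
          class = "rex_config_error")
  }

  at <- cfg$at_fraction
  genome <- sample(DNA_BASES, L, replace = TRUE,
                   prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2))

  strands <- rep(c("+", "-"), length.out = n)
  near <- runif(n) < cfg$frac_near_gene
  hypo <- runif(n) < cfg$frac_hypothetical
  products <- c("alcohol dehydrogenase", "ABC transporter ATP-binding protein",
                "iron hydrogenase", "transcriptional regulator",
                "sporulation protein", "solute-binding protein")

  planted <- vector("list", n)
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    s0 <- (i - 1L) * slot               # 0-based slot origin
    site_seq <- sample_accepted_site(p)
    gap <- if (near[i]) sample(0:120, 1) else sample(201:320, 1) - len
    gene_len <- sample(200:600, 1)
    if (strands[i] == "+") {
      site_start <- s0 + 10L
      gene_start <- site_start + len + gap
      gene_end <- min(gene_start + gene_len, s0 + slot - 5L)
    } else {
      site_start <- s0 + slot - 10L - len
      gene_end <- site_start - gap
      gene_start <- max(gene_end - gene_len, s0 + 5L)
    }
    if (gene_start >= gene_end) {
      abort("infeasible packing: no room for a gene in its slot.",
            class = "rex_config_error")
    }
    forward <- if (strands[i] == "+") site_seq else reverse_complement(site_seq)
    genome[(site_start + 1L):(site_start + len)] <- chars(forward)
    planted[[i]] <- tibble(contig = cfg$contig, start = site_start,
                           strand = strands[i], site_seq = site_seq)
    genes[[i]] <- tibble(
      contig = cfg$contig, start = as.integer(gene_start),
      end = as.integer(gene_end), strand = strands[i],
      locus_tag = sprintf("SYN_%04d", i * 5L),
      gene_name = NA_character_,
      product = if (hypo[i]) "hypothetical protein" else sample_one(products)
    )
  }
  genes <- bind_rows(genes)
  seq_str <- paste0(genome, collapse = "")

  # completeness: record every window the pattern accepts, planted or not
  hits <- scan_sequence(seq_str, p, contig = cfg$contig)
  planted_df <- bind_rows(planted)
  truth_sites <- mutate(hits,
                        planted = .data$start %in% planted_df$start)

  truth <- list(
    planted_sites = truth_sites,
    genes = genes,
    expected_regulon = expected_regulon_from_truth(truth_sites, genes)
  )
  if (!is.null(fasta_path)) {
    dss <- Biostrings::DNAStringSet(setNames(seq_str, cfg$contig))
    Biostrings::writeXStringSet(dss, fasta_path)
  }
  list(sequence = seq_str, contig = cfg$contig, truth = truth, config = cfg)
}

# Ground-truth regulon computed by plain coordinate arithmetic over the
# truth tables (independent of annotate_sites/filter_sites).
expected_regulon_from_truth <- function(sites, genes, max_upstream = 200,
                                        deny_list = c("hypothetical protein", "")) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s_start <- sites$start[i]; s_end <- s_start + nchar(sites$forward_seq[i])
    g <- genes[genes$contig == sites$contig[i], ]
    if (any(g$start < s_end & s_start < g$end)) next
    best <- NULL; best_d <- Inf
    for (j in seq_len(nrow(g))) {
      if (g$strand[j] == "+" && g$start[j] >= s_end) {
        d <- g$start[j] - s_start
      } else if (g$strand[j] == "-" && g$end[j] <= s_start) {
        d <- s_end - g$end[j]
      } else next
      if (d < best_d || (d == best_d && g$strand[j] == "+")) {
        best_d <- d; best <- j
      }
    }
    if (is.null(best)) next
    if (best_d > max_upstream) next
    prod <- g$product[best]
    if (is.na(prod) || tolower(trimws(prod)) %in% tolower(deny_list)) next
    rows[[length(rows) + 1L]] <- tibble(
      locus_tag = g$locus_tag[best], start = s_start,
      distance = -as.integer(best_d)
    )
  }
  bind_rows(rows)
}

#' Write synthetic gene features as GFF3
#'
#' @param truth Truth list from [gen_genome()] (or any feature tibble in its
#'   `genes` slot).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
gen_gff <- function(truth, path) {
  genes <- if (is.data.frame(truth)) truth else truth$genes
  if (anyDuplicated(genes$locus_tag)) {
    abort("locus_tag values must be unique.", class = "rex_input_error")
  }
  esc <- function(x) {
    x <- ifelse(is.na(x), "", x)
    gsub("([;=,&])", "", x)  # keep attribute values GFF3-clean
  }
  lines <- c("##gff-version 3")
  if (nrow(genes) > 0) {
    attrs <- sprintf("ID=%s;locus_tag=%s;product=%s",
                     esc(genes$locus_tag), esc(genes$locus_tag),
                     esc(genes$product))
    attrs <- ifelse(is.na(genes$gene_name), attrs,
                    paste0(attrs, ";gene=", esc(genes$gene_name)))
    lines <- c(lines, sprintf("%s\trexreg\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              genes$contig, genes$start + 1L, genes$end,
                              genes$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate logistic OD600 growth curves with known rates
#'
#' `OD(t) = K * od0 * exp(mu t) / (K + od0 * (exp(mu t) - 1))`, optionally
#' perturbed by multiplicative lognormal noise.
#'
#' @param true_mu Named numeric vector, strain -> maximal growth rate (1/h).
#' @param K Carrying capacity (scalar or named per strain).
#' @param od0 Inoculation OD600 (default 0.002, a 1% v/v transfer).
#' @param dt Sampling interval in hours (default 0.05, a 3-minute plate
#'   reader cycle).
#' @param t_max Duration in hours.
#' @param noise_sd Standard deviation of log-scale multiplicative noise.
#' @param seed Integer seed.
#' @return List with `od_table` (strain, time_h, od600) and `truth` (strain,
#'   mu, K, max_od_true -- the maximum of the noise-free curve).
#' @export
gen_od_curves <- function(true_mu, K = 0.43, od0 = 0.002, dt = 0.05,
                          t_max = 72, noise_sd = 0, seed = 1) {
  if (is.null(names(true_mu)) || any(names(true_mu) == "")) {
    abort("`true_mu` must be a named vector (strain -> mu).",
          class = "rex_config_error")
  }
  if (any(K <= 0)) {
    abort("carrying capacity `K` must be positive.", class = "rex_config_error")
  }
  set.seed(seed)
  times <- seq(0, t_max, by = dt)
  Ks <- if (length(K) == 1L) setNames(rep(K, length(true_mu)), names(true_mu))
        else K[names(true_mu)]
  pieces <- purrr::imap(true_mu, function(mu, strain) {
    k <- Ks[[strain]]
    od <- k * od0 * exp(mu * times) / (k + od0 * (exp(mu * times) - 1))
    noisy <- if (noise_sd > 0) od * exp(rnorm(length(od), 0, noise_sd)) else od
    list(table = tibble(strain = strain, time_h = times, od600 = noisy),
         truth = tibble(strain = strain, mu = mu, K = k, max_od_true = max(od)))
  })
  list(od_table = bind_rows(purrr::map(pieces, "table")),
       truth = bind_rows(purrr::map(pieces, "truth")))
}

#' Generate a breakpoint-evidence table with known pass labels
#'
#' Read counts and not-perfectly-matched fractions are drawn to straddle the
#' filtering thresholds (10 reads, fraction 0.20), including exact-boundary
#' rows; the pass label of every row is then computed from the same strict
#' retention rule the filter applies.
#'
#' @param n Number of breakpoint records.
#' @param pass_fraction Approximate fraction of records drawn from the
#'   passing region.
#' @param seed Integer seed.
#' @param contig Contig identifier.
#' @param out_path Optional TSV path to write the table to.
#' @return List with `breakpoints` (contig, pos, side, read_count,
#'   frac_not_perfectly_matched, unaligned_seq) and logical `pass_label`.
#' @export
gen_breakpoint_table <- function(n = 500, pass_fraction = 0.5, seed = 1,
                                 contig = "synth_contig_1", out_path = NULL) {
  assert_scalar_number(n, "n", min = 0)
  set.seed(seed)
  want_pass <- runif(n) < pass_fraction
  read_count <- integer(n)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    if (want_pass[i]) {
      read_count[i] <- sample(10:80, 1)
      frac[i] <- round(runif(1, 0.20, 0.95), 2)
    } else {
      mode <- sample(c("reads", "frac", "both"), 1)
      read_count[i] <- if (mode %in% c("reads", "both")) sample(0:9, 1)
                       else sample(10:80, 1)
      frac[i] <- if (mode %in% c("frac", "both")) round(runif(1, 0, 0.19), 2)
                 else round(runif(1, 0.20, 0.95), 2)
    }
  }
  # deterministic boundary rows exercising the strict thresholds
  if (n >= 4) {
    if (pass_fraction > 0) { read_count[1] <- 10L; frac[1] <- 0.20 }
    read_count[2] <- 9L; frac[2] <- 0.50
    read_count[3] <- 50L; frac[3] <- 0.19
    read_count[4] <- 9L; frac[4] <- 0.19
  }
  bp <- tibble(
    contig = contig,
    pos = sort(sample.int(3e6, n)),
    side = sample(c("left", "right"), n, replace = TRUE),
    read_count = read_count,
    frac_not_perfectly_matched = frac,
    unaligned_seq = vapply(sample(20:75, n, replace = TRUE), function(l) {
      paste0(sample(DNA_BASES, l, replace = TRUE), collapse = "")
    }, "")
  )
  pass_label <- bp$read_count >= 10 & bp$frac_not_perfectly_matched >= 0.20
  if (!is.null(out_path)) readr::write_tsv(bp, out_path)
  list(breakpoints = bp, pass_label = pass_label)
}

#' Generate a fermentation end-product table from target yields
#'
#' Inverse of [percent_theoretical_yield()]: ethanol is set to
#' `p/100 * consumed * coeff` for each strain's target percent `p`; acetate
#' and lactate are filled with small plausible residuals.
#'
#' @param true_yields Named numeric vector, strain -> percent theoretical
#'   yield (values above 150 are rejected as a guard).
#' @param substrate Substrate name (default `"cellobiose"`).
#' @param consumed Substrate consumed in g/L (default 5, i.e. complete
#'   consumption of a 5 g/L bottle).
#' @param seed Integer seed for the residual products.
#' @return List with `table` (a fermentation record tibble) and `truth`.
#' @export
gen_fermentation_table <- function(true_yields, substrate = "cellobiose",
                                   consumed = 5, seed = 1) {
  if (is.null(names(true_yields)) || any(names(true_yields) == "")) {
    abort("`true_yields` must be a named vector (strain -> percent).",
          class = "rex_config_error")
  }
  if (any(true_yields < 0 | true_yields > 150)) {
    abort("target percent yields must be within [0, 150].",
          class = "rex_config_error")
  }
  set.seed(seed)
  coeff <- theoretical_yield_coeff(substrate)
  tbl <- tibble(
    strain = names(true_yields),
    substrate = substrate,
    substrate_initial = consumed,
    substrate_final = 0,
    ethanol = unname(true_yields) / 100 * consumed * coeff,
    acetate = round(runif(length(true_yields), 0.05, 0.6), 3),
    lactate = round(runif(length(true_yields), 0.01, 0.3), 3)
  )
  list(table = tbl,
       truth = tibble(strain = names(true_yields),
                      percent_theoretical = unname(true_yields)))
}

#' Generate qPCR wells and a dilution series from known copy ratios
#'
#' Sample Cq values follow the standard-curve model
#' `Cq = intercept + slope * log10(copies)` plus Gaussian noise; target
#' copies are `ratio * ref_copies` with the reference gene at ratio 1. The
#' returned standards table is a noise-free 10-fold dilution series for
#' refitting the curve.
#'
#' @param true_copy_ratios Named numeric vector, target -> copy ratio to the
#'   reference; the reference is added at ratio 1 if absent.
#' @param intercept,slope Standard-curve parameters (defaults 38 and
#'   `-log2(10)`, i.e. perfect doubling).
#' @param ref_copies Absolute copies of the reference target.
#' @param n_reps Replicate wells per target (default 6: biological duplicate
#'   x technical triplicate).
#' @param noise_sd Gaussian Cq noise standard deviation.
#' @param seed Integer seed.
#' @param reference_target Reference gene name (default `"recA"`).
#' @return List with `samples` (target, cq), `standards` (copies, cq) and
#'   `truth` (target, true_ratio).
#' @export
gen_qpcr <- function(true_copy_ratios, intercept = 38, slope = -log(10, 2),
                     ref_copies = 1e4, n_reps = 6, noise_sd = 0.1, seed = 1,
                     reference_target = "recA") {
  if (is.null(names(true_copy_ratios)) || any(names(true_copy_ratios) == "")) {
    abort("`true_copy_ratios` must be a named vector (target -> ratio).",
          class = "rex_config_error")
  }
  if (!reference_target %in% names(true_copy_ratios)) {
    true_copy_ratios <- c(true_copy_ratios, setNames(1, reference_target))
  }
  set.seed(seed)
  samples <- purrr::imap(true_copy_ratios, function(r, target) {
    copies <- r * ref_copies
    tibble(target = target,
           cq = intercept + slope * log10(copies) +
             rnorm(n_reps, 0, noise_sd))
  })
  standards <- tibble(copies = 10^(2:7))
  standards$cq <- intercept + slope * log10(standards$copies)
  list(
    samples = bind_rows(samples),
    standards = standards,
    truth = tibble(target = names(true_copy_ratios),
                   true_ratio = unname(true_copy_ratios))
  )
}
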