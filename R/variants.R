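#' Read small-variant calls from VCF or TSV
#'
#' A minimal VCF subset is supported (CHROM, POS, REF, ALT and an `AF`-style
#' fraction in INFO), read with the vcfR package; any other extension is read
#' as a TSV with columns `contig`, `pos`, `ref`, `alt`, `type`,
#' `supporting_fraction`. Variant type is inferred from allele lengths when
#' absent (equal single bases = SNV, longer alt = INS, longer ref = DEL).
#'
#' @param path Path to a `.vcf` or TSV file.
#' @return Tibble with `contig`, `pos` (1-based), `ref`, `alt`, `type`,
#'   `supporting_fraction`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("variant file not found: '%s'.", path),
          class = "rex_input_error")
  }
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("reading VCF requires the vcfR package.", class = "rex_config_error")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- vcfR::extract.info(v, "AF")
    out <- tibble(
      contig = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      supporting_fraction = suppressWarnings(as.numeric(info))
    )
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    assert_columns(out, c("contig", "pos", "ref", "alt"), "variant table")
    out <- mutate(out, pos = as.integer(.data$pos))
  }
  if (!"type" %in% names(out)) {
    out$type <- dplyr::case_when(
      nchar(gsub("-", "", out$ref)) == 1 & nchar(gsub("-", "", out$alt)) == 1 &
        out$ref != "-" & out$alt != "-" ~ "SNV",
      nchar(gsub("-", "", out$alt)) > nchar(gsub("-", "", out$ref)) ~ "INS",
      TRUE ~ "DEL"
    )
  }
  if (!"supporting_fraction" %in% names(out)) out$supporting_fraction <- NA_real_
  out
}

#' Subtract wild-type background variants
#'
#' Variants identical to a call in the control (wild-type) set -- matched
#' exactly on (contig, pos, ref, alt) -- are dropped; these typically reflect
#' errors in the reference sequence rather than new mutations. Order of the
#' surviving sample variants is preserved. A control call at the same
#' position but with a different allele does not remove the sample variant.
#'
#' @param sample,control Variant tibbles with `contig`, `pos`, `ref`, `alt`.
#' @return The sample tibble minus background-matched rows.
#' @export
subtract_background <- function(sample, control) {
  key <- c("contig", "pos", "ref", "alt")
  assert_columns(sample, key, "sample variants")
  assert_columns(control, key, "control variants")
  anti_join(sample, select(control, dplyr::all_of(key)), by = key)
}

#' Filter breakpoint evidence on read support
#'
#' Breakpoints with fewer than `min_reads` supporting reads or less than
#' `min_frac` "not perfectly matched" reads are eliminated; both boundaries
#' are inclusive for retention (a record at exactly 10 reads and fraction
#' 0.20 survives).
#'
#' @param records Breakpoint tibble with `read_count` and
#'   `frac_not_perfectly_matched` columns.
#' @param min_reads Minimum supporting reads (default 10).
#' @param min_frac Minimum not-perfectly-matched fraction (default 0.20).
#' @return The surviving rows, order preserved.
#' @export
filter_breakpoints <- function(records, min_reads = 10, min_frac = 0.20) {
  assert_scalar_number(min_reads, "min_reads", min = 0)
  assert_scalar_number(min_frac, "min_frac", min = 0)
  assert_columns(records, c("read_count", "frac_not_perfectly_matched"),
                 "breakpoints")
  filter(records, .data$read_count >= min_reads,
         .data$frac_not_perfectly_matched >= min_frac)
}

# longest common substring of a and b; "" when none
lcs_string <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  na <- length(ca); nb <- length(cb)
  if (na == 0 || nb == 0) return("")
  best_len <- 0L; best_end <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_i <- ca[i] == cb
    cur[match_i] <- c(0L, prev)[which(match_i)] + 1L
    mx <- max(cur)
    if (mx > best_len) {
      best_len <- mx
      best_end <- which.max(cur)
    }
    prev <- cur
  }
  if (best_len == 0L) return("")
  substr(b, best_end - best_len + 1L, best_end)
}

#' Pair left and right breakpoints into structural-variant calls
#'
#' Greedy nearest-first pairing: candidate pairs are a left- and a
#' right-side breakpoint on the same contig whose positions differ by at
#' most `max_span` and whose unaligned sequences share an exact substring of
#' at least `min_overlap` bases (directly or with one sequence
#' reverse-complemented). Candidates are taken in order of increasing span;
#' ties are broken by the lower right-breakpoint coordinate, then the lower
#' left coordinate. Each breakpoint is used at most once. Unpaired records
#' are reported in the `unpaired` attribute and a message.
#'
#' @param lefts,rights Filtered breakpoint tibbles with `contig`, `pos`,
#'   `read_count`, `unaligned_seq` (each at most 75 bp).
#' @param max_span Maximum distance between paired breakpoints (default 10 kb).
#' @param min_overlap Minimum shared-substring length (default 15 bp).
#' @return Tibble of calls: `contig`, `left_pos`, `right_pos`, `span`,
#'   `evidence_seq` (the longest shared substring), with attribute
#'   `unpaired` (tibble of the unused records with their side).
#' @export
pair_breakpoints <- function(lefts, rights, max_span = 10000, min_overlap = 15) {
  assert_scalar_number(max_span, "max_span", min = 0)
  assert_scalar_number(min_overlap, "min_overlap", min = 1)
  for (df in list(lefts, rights)) {
    assert_columns(df, c("contig", "pos", "unaligned_seq"), "breakpoints")
    if (any(nchar(df$unaligned_seq) > 75)) {
      abort("breakpoint unaligned sequences may be at most 75 bp.",
            class = "rex_input_error")
    }
  }
  empty <- tibble(contig = character(0), left_pos = integer(0),
                  right_pos = integer(0), span = integer(0),
                  evidence_seq = character(0))
  if (nrow(lefts) == 0 || nrow(rights) == 0) {
    attr(empty, "unpaired") <- bind_rows(
      mutate(lefts, side = "left"), mutate(rights, side = "right"))
    return(empty)
  }

  cand <- tidyr::crossing(li = seq_len(nrow(lefts)), ri = seq_len(nrow(rights)))
  cand <- mutate(cand,
                 contig_l = lefts$contig[.data$li],
                 contig_r = rights$contig[.data$ri],
                 span = abs(lefts$pos[.data$li] - rights$pos[.data$ri]))
  cand <- filter(cand, .data$contig_l == .data$contig_r,
                 .data$span <= max_span)
  if (nrow(cand) > 0) {
    cand$evidence_seq <- purrr::map2_chr(cand$li, cand$ri, function(i, j) {
      a <- toupper(lefts$unaligned_seq[i])
      b <- toupper(rights$unaligned_seq[j])
      direct <- lcs_string(a, b)
      flipped <- lcs_string(a, reverse_complement(b))
      if (nchar(direct) >= nchar(flipped)) direct else flipped
    })
    cand <- filter(cand, nchar(.data$evidence_seq) >= min_overlap)
  } else {
    cand$evidence_seq <- character(0)
  }
  cand <- arrange(cand, .data$span, rights$pos[.data$ri], lefts$pos[.data$li])

  used_l <- logical(nrow(lefts)); used_r <- logical(nrow(rights))
  picks <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand$li[k]; j <- cand$ri[k]
    if (!used_l[i] && !used_r[j]) {
      used_l[i] <- TRUE; used_r[j] <- TRUE
      picks <- c(picks, k)
    }
  }
  sel <- cand[picks, , drop = FALSE]
  out <- tibble(
    contig = sel$contig_l,
    left_pos = as.integer(lefts$pos[sel$li]),
    right_pos = as.integer(rights$pos[sel$ri]),
    span = as.integer(sel$span),
    evidence_seq = sel$evidence_seq
  )
  unpaired <- bind_rows(
    mutate(lefts[!used_l, , drop = FALSE], side = "left"),
    mutate(rights[!used_r, , drop = FALSE], side = "right")
  )
  if (nrow(unpaired) > 0) {
    inform(sprintf("%d breakpoint(s) left unpaired.", nrow(unpaired)))
  }
  attr(out, "unpaired") <- unpaired
  out
}

AA3 <- c(Biostrings::AMINO_ACID_CODE, "*" = "*")

aa3 <- function(one_letter) unname(AA3[one_letter])

translate_codon <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

#' Name the coding effect of a variant in protein nomenclature
#'
#' Translates reference and alternate codons with the standard (bacterial)
#' genetic code and names the change in the conventional style: missense as
#' `Thr597Lys`, nonsense with a `*` (`Glu454*`), frameshifting indels with an
#' `fs` suffix at the first affected residue (`Lys290fs`), in-frame indels
#' with flanking-residue notation, synonymous changes with identical
#' three-letter codes. GTG/TTG initiator codons are translated as written.
#' Variants up to 300 bp before the translational start are reported as
#' `upstream` with their signed offset. The variant's alleles are given on
#' the forward genome strand; they are complemented internally for
#' minus-strand genes. Deleted or absent alleles may be written `"-"` or
#' `""`.
#'
#' @param variant One-row tibble with `pos` (1-based), `ref`, `alt`, `type`
#'   (`SNV`, `INS`, `DEL`; insertions insert after `pos`).
#' @param gene One-row feature tibble (`start` 0-based, `end`, `strand`,
#'   `locus_tag`).
#' @param cds_seq Coding-strand CDS sequence, length divisible by 3.
#' @return One-row tibble: `locus_tag`, `kind` (`missense`, `synonymous`,
#'   `nonsense`, `frameshift`, `inframe_ins`, `inframe_del`, `upstream`),
#'   `description`, `residue` (first affected residue index, NA for
#'   upstream), `offset` (signed bp for upstream variants, NA otherwise).
#' @export
annotate_coding_effect <- function(variant, gene, cds_seq) {
  cds_seq <- assert_dna(cds_seq, "cds_seq")
  if (nchar(cds_seq) %% 3 != 0) {
    abort("`cds_seq` length must be divisible by 3.", class = "rex_input_error")
  }
  pos <- as.integer(variant$pos)
  ref <- toupper(gsub("-", "", variant$ref))
  alt <- toupper(gsub("-", "", variant$alt))
  plus <- gene$strand == "+"
  in_cds <- pos >= gene$start + 1L & pos <= gene$end

  if (!in_cds) {
    offset <- if (plus) pos - (gene$start + 1L) else gene$end - pos
    if (offset >= 0 || offset < -300L) {
      abort(sprintf(
        "variant at %d is neither inside the CDS nor within 300 bp upstream of %s.",
        pos, gene$locus_tag), class = "rex_input_error")
    }
    return(tibble(
      locus_tag = gene$locus_tag, kind = "upstream",
      description = sprintf("%d bp upstream", -offset),
      residue = NA_integer_, offset = as.integer(offset)
    ))
  }

  # map the affected genomic bases to CDS coordinates (1-based)
  ref_span <- if (nchar(ref) > 0) pos + seq_len(nchar(ref)) - 1L else integer(0)
  to_cds <- function(gpos) {
    if (plus) gpos - gene$start else gene$end - gpos + 1L
  }
  cds_ref <- if (plus) ref else reverse_complement(ref)
  cds_alt <- if (plus) alt else reverse_complement(alt)

  check_no_internal_stop <- function(last_codon) {
    if (last_codon <= 1L) return(invisible())
    upstream_codons <- substring(cds_seq, 3L * (seq_len(last_codon - 1L) - 1L) + 1L,
                                 3L * (seq_len(last_codon - 1L)))
    if (any(translate_codon(upstream_codons) == "*")) {
      abort("annotation mismatch: CDS contains an internal stop before the variant.",
            class = "rex_input_error")
    }
  }

  residue_at <- function(idx) {
    codon <- substr(cds_seq, 3L * (idx - 1L) + 1L, 3L * idx)
    translate_codon(codon)
  }

  type <- variant$type
  if (type == "SNV") {
    cpos <- to_cds(pos)
    codon_idx <- ceiling(cpos / 3)
    check_no_internal_stop(codon_idx)
    codon <- substr(cds_seq, 3L * (codon_idx - 1L) + 1L, 3L * codon_idx)
    within <- cpos - 3L * (codon_idx - 1L)
    if (substr(codon, within, within) != cds_ref) {
      abort(sprintf(
        "annotation mismatch: CDS has %s at codon %d position %d, variant ref is %s.",
        substr(codon, within, within), codon_idx, within, cds_ref),
        class = "rex_input_error")
    }
    new_codon <- codon
    substr(new_codon, within, within) <- cds_alt
    ref_aa <- translate_codon(codon)
    alt_aa <- translate_codon(new_codon)
    kind <- if (alt_aa == ref_aa) "synonymous"
            else if (alt_aa == "*") "nonsense" else "missense"
    desc <- paste0(aa3(ref_aa), codon_idx,
                   if (alt_aa == "*") "*" else aa3(alt_aa))
    return(tibble(locus_tag = gene$locus_tag, kind = kind, description = desc,
                  residue = as.integer(codon_idx), offset = NA_integer_))
  }

  if (type == "DEL") {
    cds_positions <- sort(to_cds(ref_span))
    first <- cds_positions[1]
    res1 <- ceiling(first / 3)
    check_no_internal_stop(res1)
    if (length(cds_positions) %% 3 != 0) {
      desc <- paste0(aa3(residue_at(res1)), res1, "fs")
      return(tibble(locus_tag = gene$locus_tag, kind = "frameshift",
                    description = desc, residue = as.integer(res1),
                    offset = NA_integer_))
    }
    res2 <- ceiling(cds_positions[length(cds_positions)] / 3)
    desc <- if (res1 == res2) {
      paste0(aa3(residue_at(res1)), res1, "del")
    } else {
      paste0(aa3(residue_at(res1)), res1, "_", aa3(residue_at(res2)), res2, "del")
    }
    return(tibble(locus_tag = gene$locus_tag, kind = "inframe_del",
                  description = desc, residue = as.integer(res1),
                  offset = NA_integer_))
  }

  if (type == "INS") {
    # inserted after `pos` on the forward strand
    ins_point <- if (plus) to_cds(pos) else to_cds(pos + 1L)  # CDS base before the insert
    res_left <- ceiling(ins_point / 3)
    check_no_internal_stop(res_left)
    if (nchar(cds_alt) %% 3 != 0) {
      res_first <- ceiling((ins_point + 1L) / 3)
      desc <- paste0(aa3(residue_at(res_first)), res_first, "fs")
      return(tibble(locus_tag = gene$locus_tag, kind = "frameshift",
                    description = desc, residue = as.integer(res_first),
                    offset = NA_integer_))
    }
    res_right <- res_left + 1L
    ins_codons <- substring(cds_alt, 3L * (seq_len(nchar(cds_alt) / 3) - 1L) + 1L,
                            3L * seq_len(nchar(cds_alt) / 3))
    ins_aa <- paste0(aa3(translate_codon(ins_codons)), collapse = "")
    desc <- paste0(aa3(residue_at(res_left)), res_left, "_",
                   aa3(residue_at(res_right)), res_right, "ins", ins_aa)
    return(tibble(locus_tag = gene$locus_tag, kind = "inframe_ins",
                  description = desc, residue = as.integer(res_left),
                  offset = NA_integer_))
  }

  abort(sprintf("unknown variant type '%s'.", type), class = "rex_input_error")
}

#' Parse a coding-effect description back to its parts
#'
#' Inverse of the nomenclature written by [annotate_coding_effect()] for
#' substitutions, nonsense and frameshift descriptions.
#'
#' @param description String such as `"Thr597Lys"`, `"Glu454*"` or
#'   `"Lys290fs"`.
#' @return List with `ref_aa` (three-letter), `residue` (integer) and `alt`
#'   (three-letter code, `"*"` or `"fs"`).
#' @export
parse_coding_description <- function(description) {
  m <- regmatches(description,
                  regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|\\*|fs)$",
                          description))[[1]]
  if (length(m) != 4L) {
    abort(sprintf("cannot parse coding description '%s'.", description),
          class = "rex_input_error")
  }
  list(ref_aa = m[2], residue = as.integer(m[3]), alt = m[4])
}
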