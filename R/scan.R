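#' Reverse complement of DNA sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] restricted
#' to unambiguous DNA. An involution: applying it twice returns the input.
#'
#' @param seq Character vector of A/C/G/T sequences (any length, `""` allowed).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("TAGTTAAATTTATAACAA")
#' @export
reverse_complement <- function(seq) {
  seq <- assert_dna(seq, "sequence")
  if (length(seq) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Scan one contig for operator sites on both strands
#'
#' Slides the pattern window across every offset of `seq` and tests the
#' window as written and as its reverse complement. A window passing in one
#' orientation is emitted once with strand `"+"` or `"-"`; a window passing in
#' both is a single row with strand `"both"` (its mismatch/spacer statistics
#' are reported from the forward orientation). `forward_seq` is always the
#' slice of the forward genome strand. Windows containing ambiguity codes are
#' skipped and counted in the `n_skipped` attribute (with an informative
#' message), not treated as errors. Overlapping hits at different offsets are
#' all kept.
#'
#' @param seq Contig sequence (single string). Shorter than one window yields
#'   an empty result, not an error.
#' @param p A [compile_pattern()] object.
#' @param contig Contig identifier recorded in the output.
#' @param circular If `TRUE`, windows are allowed to wrap from the end of the
#'   contig back to its start (their `start` stays in `[0, L)` and `end` may
#'   exceed `L`).
#' @return Tibble of site hits: `contig`, `start` (0-based), `end` (half-open,
#'   `start + 18`), `strand` (`+`, `-`, `both`), `forward_seq`,
#'   `arm_mismatch_position` (0, 4 or 5), `spacer_gc_count`; sorted by
#'   `(contig, start)`, with attribute `n_skipped`.
#' @export
scan_sequence <- function(seq, p, contig = "seq1", circular = FALSE) {
  stopifnot(inherits(p, "rex_pattern"), is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  len <- window_length(p)
  L <- nchar(seq)

  empty <- tibble(
    contig = character(0), start = integer(0), end = integer(0),
    strand = character(0), forward_seq = character(0),
    arm_mismatch_position = integer(0), spacer_gc_count = integer(0)
  )
  if (L < len) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }

  scan_seq <- if (circular) paste0(seq, substr(seq, 1L, len - 1L)) else seq
  starts <- 0:(if (circular) L - 1L else L - len)  # 0-based offsets

  cv <- chars(scan_seq)
  bad <- cumsum(!(cv %in% DNA_BASES))
  n_bad_in <- bad[starts + len] - c(0L, bad)[starts + 1L]
  valid <- n_bad_in == 0L
  n_skipped <- sum(!valid)
  if (n_skipped > 0) {
    inform(sprintf("contig %s: skipped %d window(s) containing ambiguity codes.",
                   contig, n_skipped))
  }
  starts <- starts[valid]
  if (length(starts) == 0) {
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }

  windows <- substring(scan_seq, starts + 1L, starts + len)
  m_f <- match_window(windows, p)
  m_r <- match_window(reverse_complement(windows), p)

  hit <- m_f$matched | m_r$matched
  out <- tibble(
    contig = contig,
    start = as.integer(starts[hit]),
    end = as.integer(starts[hit] + len),
    strand = dplyr::case_when(
      m_f$matched[hit] & m_r$matched[hit] ~ "both",
      m_f$matched[hit] ~ "+",
      TRUE ~ "-"
    ),
    forward_seq = windows[hit],
    arm_mismatch_position = ifelse(m_f$matched[hit],
                                   m_f$arm_mismatch_position[hit],
                                   m_r$arm_mismatch_position[hit]),
    spacer_gc_count = ifelse(m_f$matched[hit],
                             m_f$spacer_gc_count[hit],
                             m_r$spacer_gc_count[hit])
  )
  out <- arrange(out, .data$contig, .data$start)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Scan a (multi-record) FASTA genome for operator sites
#'
#' Reads the FASTA with [Biostrings::readDNAStringSet()] and concatenates
#' [scan_sequence()] over the records. Contig identifiers are the first
#' whitespace-delimited token of each FASTA header.
#'
#' @param fasta_path Path to a FASTA file.
#' @inheritParams scan_sequence
#' @return Tibble of site hits as in [scan_sequence()], with attribute
#'   `n_skipped` summed over contigs.
#' @export
scan_genome <- function(fasta_path, p, circular = FALSE) {
  if (!is.character(fasta_path) || length(fasta_path) != 1L ||
      !file.exists(fasta_path)) {
    abort(sprintf("FASTA file not found: '%s'.", fasta_path),
          class = "rex_input_error")
  }
  recs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) abort(sprintf("could not read FASTA '%s': %s",
                                      fasta_path, conditionMessage(e)),
                              class = "rex_input_error")
  )
  if (length(recs) == 0) {
    abort(sprintf("FASTA '%s' contains no records.", fasta_path),
          class = "rex_input_error")
  }
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate contig id(s) in '%s': %s.", fasta_path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "rex_input_error")
  }
  pieces <- lapply(seq_along(recs), function(i) {
    scan_sequence(as.character(recs[[i]]), p, contig = ids[i],
                  circular = circular)
  })
  out <- bind_rows(pieces)
  attr(out, "n_skipped") <- sum(vapply(pieces, attr, 0L, "n_skipped"))
  out
}

#' Write site hits as TSV or BED6
#'
#' @param sites Tibble from [scan_genome()]/[scan_sequence()].
#' @param path Output path.
#' @param format `"tsv"` (all columns, 0-based starts) or `"bed"` (BED6 with
#'   score 0 and the forward-strand sequence as name; strand `"both"` is
#'   written as `"."`).
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  assert_columns(sites, c("contig", "start", "end", "strand", "forward_seq"),
                 "sites")
  if (format == "tsv") {
    readr::write_tsv(sites, path)
  } else {
    bed <- tibble(
      chrom = sites$contig, start = sites$start, end = sites$end,
      name = sites$forward_seq, score = 0L,
      strand = ifelse(sites$strand == "both", ".", sites$strand)
    )
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}
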