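#' Read gene features from GFF3 or a tabular fallback
#'
#' GFF3 (`.gff`/`.gff3`) is parsed with [rtracklayer::import()]; `gene`
#' records are used when present, otherwise `CDS`. Anything else is read as a
#' 7-column TSV (`contig`, `start`, `end`, `strand`, `locus_tag`,
#' `gene_name`, `product`) whose `start` is already 0-based. GFF3 coordinates
#' (1-based inclusive) are converted to the package's 0-based half-open
#' convention.
#'
#' @param path Path to a GFF3 or TSV feature file.
#' @return Tibble of features: `contig`, `start` (0-based), `end` (half-open),
#'   `strand` (`+`/`-`), `locus_tag`, `gene_name`, `product`.
#' @export
read_gene_features <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("feature file not found: '%s'.", path),
          class = "rex_input_error")
  }
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    types <- as.character(gr$type)
    keep <- if (any(types == "gene")) types == "gene" else types == "CDS"
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    grab <- function(nm, alt = NULL) {
      v <- if (nm %in% names(mc)) as.character(mc[[nm]]) else rep(NA_character_, length(gr))
      if (!is.null(alt)) {
        miss <- is.na(v)
        if (alt %in% names(mc)) v[miss] <- as.character(mc[[alt]])[miss]
      }
      v
    }
    out <- tibble(
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      locus_tag = grab("locus_tag", "ID"),
      gene_name = grab("gene", "Name"),
      product = grab("product")
    )
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    assert_columns(out, c("contig", "start", "end", "strand", "locus_tag",
                          "gene_name", "product"), "feature table")
    out <- mutate(out, start = as.integer(.data$start), end = as.integer(.data$end))
  }
  if (!all(out$strand %in% c("+", "-"))) {
    abort("gene features must have strand '+' or '-'.", class = "rex_input_error")
  }
  if (anyDuplicated(out$locus_tag)) {
    abort("locus_tag values must be unique per genome.", class = "rex_input_error")
  }
  out
}

#' Nearest downstream gene of a single site
#'
#' A site annotates a gene when it lies strictly in the gene's upstream
#' intergenic region: entirely before the gene's translational start on the
#' gene's own strand and overlapping no gene body at all. The signed distance
#' follows the reporting convention that includes the site's own length: it is
#' measured from the site boundary farthest from the gene, so for a `+` gene
#' `|distance| = gene_start - site_start` and for a `-` gene
#' `|distance| = site_end - gene_end`; retained distances are always negative
#' (upstream) and never smaller in magnitude than the window length.
#'
#' @param site One-row tibble (or list) with `contig`, `start`, `end`.
#' @param features Feature tibble from [read_gene_features()].
#' @return `NULL` when the site overlaps a gene body or no downstream gene
#'   exists on either side; otherwise a list with `gene` (one-row tibble) and
#'   `distance` (negative integer).
#' @export
nearest_downstream_gene <- function(site, features) {
  assert_columns(features, c("contig", "start", "end", "strand", "locus_tag"),
                 "features")
  feats <- filter(features, .data$contig == site$contig)
  if (nrow(feats) == 0) {
    abort(sprintf("no features on contig '%s' (contig mismatch?).", site$contig),
          class = "rex_input_error")
  }
  overlaps <- feats$start < site$end & site$start < feats$end
  if (any(overlaps)) return(NULL)

  plus <- filter(feats, .data$strand == "+", .data$start >= site$end)
  minus <- filter(feats, .data$strand == "-", .data$end <= site$start)
  cand <- bind_rows(
    if (nrow(plus) > 0) mutate(plus, .dist = .data$start - site$start),
    if (nrow(minus) > 0) mutate(minus, .dist = site$end - .data$end)
  )
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  cand <- arrange(cand, .data$.dist, .data$strand, .data$start)  # ties: "+" first
  best <- cand[1, ]
  list(gene = select(best, -".dist"), distance = -as.integer(best$.dist))
}

#' Annotate site hits with their nearest downstream gene
#'
#' Vectorized wrapper over [nearest_downstream_gene()]: sites overlapping a
#' gene body, or with no downstream gene on either side, are dropped (a
#' message reports how many).
#'
#' @param sites Site tibble from [scan_genome()].
#' @param features Feature tibble from [read_gene_features()].
#' @return The retained sites with `locus_tag`, `gene_name`, `product` and
#'   signed `distance` columns appended.
#' @export
annotate_sites <- function(sites, features) {
  assert_columns(sites, c("contig", "start", "end"), "sites")
  if (nrow(sites) == 0) {
    return(mutate(sites, locus_tag = character(0), gene_name = character(0),
                  product = character(0), distance = integer(0)))
  }
  ann <- purrr::map(seq_len(nrow(sites)), function(i) {
    hit <- nearest_downstream_gene(sites[i, ], features)
    if (is.null(hit)) return(NULL)
    mutate(sites[i, ],
           locus_tag = hit$gene$locus_tag,
           gene_name = hit$gene$gene_name,
           product = hit$gene$product,
           distance = hit$distance)
  })
  dropped <- sum(vapply(ann, is.null, TRUE))
  if (dropped > 0) {
    inform(sprintf("%d site(s) dropped (gene overlap or no downstream gene).",
                   dropped))
  }
  bind_rows(ann)
}

#' Apply the upstream-distance and annotation filters
#'
#' Removes sites farther than `max_upstream` from their gene (strict: a site
#' exactly at the boundary is retained) and, when `require_annotation` is
#' set, sites whose gene product is missing or matches the deny list
#' (case-insensitive). Input order is preserved.
#'
#' @param annotated Tibble from [annotate_sites()].
#' @param max_upstream Maximum upstream distance magnitude in bp (default 200).
#' @param require_annotation Drop sites upstream of unannotated genes?
#' @param deny_list Product strings treated as "not annotated".
#' @return The filtered tibble.
#' @export
filter_sites <- function(annotated, max_upstream = 200,
                         require_annotation = TRUE,
                         deny_list = c("hypothetical protein", "")) {
  assert_scalar_number(max_upstream, "max_upstream", min = 0)
  assert_columns(annotated, c("distance", "product"), "annotated sites")
  out <- filter(annotated, abs(.data$distance) <= max_upstream)
  if (require_annotation) {
    prod_norm <- tolower(trimws(dplyr::coalesce(out$product, "")))
    out <- out[!(prod_norm %in% tolower(trimws(deny_list))), ]
  }
  out
}

#' Strand-correct a site to its matching orientation
#'
#' Returns the window in the orientation in which it passes the pattern:
#' the forward-strand sequence for `+` and `both` hits, its reverse
#' complement for `-` hits. Used to stack sites before consensus building.
#'
#' @param site Tibble of sites (any number of rows) with `strand` and
#'   `forward_seq`.
#' @return Character vector of oriented windows.
#' @export
orient_site <- function(site) {
  assert_columns(site, c("strand", "forward_seq"), "site")
  out <- site$forward_seq
  flip <- site$strand == "-"
  if (any(flip)) out[flip] <- reverse_complement(out[flip])
  out
}

#' Build a threshold consensus from oriented site sequences
#'
#' Per-column base frequencies are computed over the stacked (strand
#' corrected) windows; a column is written as a concrete base when that
#' base's frequency reaches `threshold`, otherwise as `N`.
#'
#' @param oriented_seqs Character vector of equal-length oriented windows
#'   (at least one).
#' @param threshold Column agreement fraction in (0.5, 1].
#' @return An object of class `rex_consensus`: list with `consensus` (string
#'   over A/C/G/T/N), `threshold`, `counts` (4 x width base count matrix) and
#'   `oriented_seqs`.
#' @examples
#' build_consensus(c("TTGTTAAATGAATAACAA", "TTGTTAATAAATTAACAC",
#'                   "TTGTTATAAATTTAACTA"), threshold = 1)
#' @export
build_consensus <- function(oriented_seqs, threshold = 1.0) {
  oriented_seqs <- assert_dna(oriented_seqs, "oriented_seqs")
  if (length(oriented_seqs) == 0) {
    abort("at least one sequence is required.", class = "rex_input_error")
  }
  if (length(unique(nchar(oriented_seqs))) != 1L) {
    abort("sequences must all have the same length.", class = "rex_input_error")
  }
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must be in (0.5, 1].", class = "rex_config_error")
  }
  counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(oriented_seqs))
  counts <- counts[DNA_BASES, , drop = FALSE]
  freq <- sweep(counts, 2L, colSums(counts), "/")
  letters <- apply(freq, 2L, function(col) {
    top <- which.max(col)
    if (col[top] >= threshold) DNA_BASES[top] else "N"
  })
  structure(
    list(consensus = paste0(letters, collapse = ""),
         threshold = threshold,
         counts = counts,
         oriented_seqs = oriented_seqs),
    class = "rex_consensus"
  )
}

#' @export
print.rex_consensus <- function(x, ...) {
  cat("<rex_consensus> ", x$consensus, "\n", sep = "")
  cat("  ", length(x$oriented_seqs), " sequence(s), threshold ",
      format(x$threshold), "\n", sep = "")
  invisible(x)
}

#' @rdname build_consensus
#' @param object,x A `rex_consensus` object.
#' @param ... Unused.
#' @method tidy rex_consensus
#' @export
tidy.rex_consensus <- function(x, ...) {
  freq <- sweep(x$counts, 2L, colSums(x$counts), "/")
  tibble(
    position = rep(seq_len(ncol(freq)), each = nrow(freq)),
    base = rep(rownames(freq), times = ncol(freq)),
    count = as.vector(x$counts),
    frequency = as.vector(freq)
  )
}

#' @rdname build_consensus
#' @method autoplot rex_consensus
#' @export
autoplot.rex_consensus <- function(object, ...) {
  df <- tidy(object)
  cons <- tibble(position = seq_len(nchar(object$consensus)),
                 letter = chars(object$consensus))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(data = cons, inherit.aes = FALSE, vjust = 0,
                       ggplot2::aes(x = .data$position, y = 4.9,
                                    label = .data$letter), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_x_continuous(breaks = unique(df$position),
                                expand = c(0, 0.2)) +
    ggplot2::labs(x = "position in window", y = NULL, fill = "freq") +
    ggplot2::theme_minimal()
}

#' Write the regulon report
#'
#' One row per retained annotated site, in the shape of a regulon summary
#' table: locus tag, gene name, product, forward-strand site sequence, signed
#' upstream distance, strand and coordinates. Two sites upstream of one gene
#' yield two rows with the same locus tag.
#'
#' @param sites Filtered, annotated site tibble.
#' @param out_path Output TSV path.
#' @return Number of data rows written, invisibly-visible (returned).
#' @export
write_regulon_report <- function(sites, out_path) {
  cols <- c("locus_tag", "gene_name", "product", "forward_seq", "distance",
            "strand", "start", "end")
  if (nrow(sites) == 0) {
    sites <- tibble(locus_tag = character(0), gene_name = character(0),
                    product = character(0), forward_seq = character(0),
                    distance = integer(0), strand = character(0),
                    start = integer(0), end = integer(0))
  }
  assert_columns(sites, cols, "annotated sites")
  report <- rename(select(as_tibble(sites), dplyr::all_of(cols)),
                   sequence = "forward_seq")
  tryCatch(
    readr::write_tsv(report, out_path),
    error = function(e) abort(sprintf("cannot write report to '%s': %s",
                                      out_path, conditionMessage(e)),
                              class = "rex_input_error")
  )
  nrow(report)
}
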