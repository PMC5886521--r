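#' Published putative Rex-binding sites of T. saccharolyticum
#'
#' The 29 reported operator sites (locus tag of the nearest downstream gene,
#' gene name where known, product, functional category, site sequence and
#' signed upstream distance). Twenty-eight sequences are 18-mers; the
#' Tsac_0706 row is printed as 19 bases and is kept as printed. Useful as an
#' acceptance suite for the scanner: every sequence should be matched by the
#' union pattern on at least one strand.
#'
#' @return Tibble with columns `locus_tag`, `gene`, `product`, `category`,
#'   `sequence`, `distance`.
#' @examples
#' sites <- rex_reference_sites()
#' table(nchar(sites$sequence))
#' @export
rex_reference_sites <- function() {
  path <- system.file("extdata", "tsac_rex_sites.tsv", package = "rexreg",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    locus_tag = "c", gene = "c", product = "c",
                    category = "c", sequence = "c", distance = "i"
                  ))
}
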