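# Internal validation helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# W = A or T; N = any base. The only degeneracy codes the pattern syntax uses.
ARM_ALPHABET <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"),
  N = c("A", "C", "G", "T")
)

is_dna <- function(x) {
  grepl("^[ACGT]*$", x)
}

#' @noRd
assert_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- !is_dna(x)
  if (any(bad)) {
    offending <- unique(gsub("[ACGT]", "", x[bad]))
    abort(sprintf(
      "%s contains non-ACGT characters (%s); only unambiguous DNA is accepted.",
      what, paste(offending, collapse = "")
    ), class = "rex_input_error")
  }
  x
}

assert_scalar_number <- function(x, what, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what),
          class = "rex_config_error")
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", what, min, x),
          class = "rex_config_error")
  }
  invisible(x)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ), class = "rex_input_error")
  }
  invisible(df)
}

# split one string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
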