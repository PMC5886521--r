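#' Compile a palindromic site pattern from its search-syntax string
#'
#' The Rex operator is searched as an 18-bp degenerate palindrome: a 5-bp
#' AT-rich arm (template `WTGWW`, where `W` = A or T), an 8-bp AT-rich spacer
#' allowed to carry at most one C or G, and the reverse complement of the arm.
#' The search syntax writes the arm template, the spacer in braces, and then
#' the five arm-2 positions as back-references `-5-4-3-2-1` (arm-2 position 1
#' pairs with arm-1 position 5, and so on). Replacing a digit with `N` frees
#' that arm-2 position, i.e. permits a mismatch against the perfect palindrome
#' there.
#'
#' Three variants make up the published search: `WTGWW{WWWWWWWW}-5-4-3-2-1`
#' (exact palindrome), `...-5-4-3-N-1` and `...-5-4-3-2-N` (one mismatch in
#' one of the last two arm positions). The reserved token `"paper-union"`
#' compiles their union: at most one arm-2 mismatch, confined to positions 4
#' and 5. Stray citation markup such as `[1]` embedded in a printed syntax
#' string is stripped before parsing.
#'
#' @param spec Pattern string in the syntax above, or `"paper-union"`.
#' @return An object of class `rex_pattern`: a list with elements
#'   `arm_template` (character vector of 5 symbols), `spacer_len` (8),
#'   `max_spacer_gc` (1), `allowed_arm2_mismatch_positions` (integer vector,
#'   1-based arm-2 positions) and `max_arm_mismatches` (0 or 1).
#' @examples
#' compile_pattern("WTGWW{WWWWWWWW}-5-4-3-2-1")
#' compile_pattern("paper-union")
#' @export
compile_pattern <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec)) {
    abort("`spec` must be a single pattern string.", class = "rex_parse_error")
  }
  if (identical(spec, "paper-union")) {
    return(new_rex_pattern(
      arm_template = c("W", "T", "G", "W", "W"),
      allowed = c(4L, 5L),
      max_mm = 1L,
      canonical = "paper-union"
    ))
  }

  raw <- toupper(gsub("\\[[^]]*\\]", "", spec))  # drop citation-markup tokens
  raw <- gsub("\\s+", "", raw)

  if (lengths(regmatches(raw, gregexpr("\\{", raw))) !=
      lengths(regmatches(raw, gregexpr("\\}", raw))) ||
      !grepl("\\{", raw)) {
    abort(sprintf("malformed pattern '%s': unbalanced or missing braces.", spec),
          class = "rex_parse_error")
  }

  m <- regmatches(raw, regexec("^([A-Z]+)\\{([A-Z]+)\\}((?:-(?:[0-9]|N))+)$", raw))[[1]]
  if (length(m) != 4L) {
    abort(sprintf("malformed pattern '%s': expected ARM{SPACER}-5-4-3-2-1 form.", spec),
          class = "rex_parse_error")
  }
  arm <- chars(m[2])
  spacer <- chars(m[3])

  bad_arm <- setdiff(arm, c("A", "C", "G", "T", "W"))
  if (length(bad_arm) > 0) {
    abort(sprintf("unknown arm code '%s' in '%s' (allowed: A,C,G,T,W).",
                  bad_arm[1], spec), class = "rex_parse_error")
  }
  if (length(arm) != 5L) {
    abort(sprintf("arm template '%s' must be exactly 5 symbols (got %d).",
                  m[2], length(arm)), class = "rex_parse_error")
  }
  if (!all(spacer == "W")) {
    abort(sprintf("spacer template '%s' must be all W.", m[3]),
          class = "rex_parse_error")
  }
  if (length(spacer) != 8L) {
    abort(sprintf("spacer template '%s' must be exactly 8 symbols (got %d).",
                  m[3], length(spacer)), class = "rex_parse_error")
  }

  toks <- chars(gsub("-", "", m[4]))
  if (length(toks) != 5L) {
    abort(sprintf("arm-2 reference list '%s' must have 5 tokens.", m[4]),
          class = "rex_parse_error")
  }
  allowed <- integer(0)
  for (i in seq_len(5L)) {
    expect_digit <- as.character(6L - i)
    if (toks[i] == "N") {
      allowed <- c(allowed, i)
    } else if (toks[i] != expect_digit) {
      abort(sprintf("arm-2 reference token '%s' at slot %d must be '%s' or 'N'.",
                    toks[i], i, expect_digit), class = "rex_parse_error")
    }
  }
  new_rex_pattern(
    arm_template = arm,
    allowed = as.integer(allowed),
    max_mm = if (length(allowed) > 0) 1L else 0L,
    canonical = raw
  )
}

new_rex_pattern <- function(arm_template, allowed, max_mm, canonical) {
  structure(
    list(
      arm_template = arm_template,
      spacer_len = 8L,
      max_spacer_gc = 1L,
      allowed_arm2_mismatch_positions = allowed,
      max_arm_mismatches = max_mm,
      canonical = canonical
    ),
    class = "rex_pattern"
  )
}

#' @export
format.rex_pattern <- function(x, ...) x$canonical

#' @export
print.rex_pattern <- function(x, ...) {
  cat("<rex_pattern> ", x$canonical, "\n", sep = "")
  cat("  arm template: ", paste(x$arm_template, collapse = ""),
      "  spacer: ", x$spacer_len, " bp (<= ", x$max_spacer_gc, " G/C)\n", sep = "")
  if (x$max_arm_mismatches > 0) {
    cat("  arm-2 mismatches: <= ", x$max_arm_mismatches, " at position(s) ",
        paste(x$allowed_arm2_mismatch_positions, collapse = ","), "\n", sep = "")
  } else {
    cat("  arm-2: exact reverse complement of arm 1\n")
  }
  invisible(x)
}

window_length <- function(p) 10L + p$spacer_len

#' Expected second arm of a perfect palindromic site
#'
#' Arm 2 of a perfect operator palindrome is the reverse complement of arm 1
#' (arm-2 position i is the complement of arm-1 position 6 - i).
#'
#' @param arm1 A concrete A/C/G/T 5-mer (vectorized).
#' @return The reverse-complement 5-mer(s).
#' @examples
#' expected_arm2("TTGTT")  # "AACAA"
#' @export
expected_arm2 <- function(arm1) {
  arm1 <- assert_dna(arm1, "arm1")
  if (any(nchar(arm1) != 5L)) {
    abort("`arm1` must be a 5-mer.", class = "rex_input_error")
  }
  reverse_complement(arm1)
}

#' Decide whether an 18-mer window is an accepted operator site
#'
#' A window matches when (a) its first 5 bases satisfy the arm template,
#' (b) its 8-bp spacer carries at most `max_spacer_gc` C/G bases, and (c) its
#' last 5 bases equal the reverse complement of the first 5 except for at most
#' `max_arm_mismatches` mismatches, each confined to the pattern's allowed
#' arm-2 positions. An arm-2 position that happens to equal the complement
#' base counts as a match, never as a mismatch, even when the pattern would
#' tolerate a mismatch there.
#'
#' @param window Character vector of concrete A/C/G/T 18-mers.
#' @param p A [compile_pattern()] object.
#' @return A tibble with one row per window: `matched` (logical),
#'   `arm_mismatch_position` (0 when the matching orientation is a perfect
#'   palindrome, otherwise the 1-based arm-2 position of the tolerated
#'   mismatch) and `spacer_gc_count`.
#' @examples
#' p <- compile_pattern("paper-union")
#' match_window("TTGTTAAATGAATAACAA", p)
#' @export
match_window <- function(window, p) {
  stopifnot(inherits(p, "rex_pattern"))
  w <- assert_dna(window, "window")
  len <- window_length(p)
  if (any(nchar(w) != len)) {
    abort(sprintf("windows must be exactly %d bp.", len), class = "rex_input_error")
  }
  if (length(w) == 0) {
    return(tibble(matched = logical(0), arm_mismatch_position = integer(0),
                  spacer_gc_count = integer(0)))
  }

  base_at <- function(j) substr(w, j, j)

  arm_ok <- rep(TRUE, length(w))
  for (j in 1:5) {
    arm_ok <- arm_ok & base_at(j) %in% ARM_ALPHABET[[p$arm_template[j]]]
  }

  gc <- rep(0L, length(w))
  for (j in 6:(5L + p$spacer_len)) {
    gc <- gc + (base_at(j) %in% c("C", "G"))
  }

  arm2_off <- 5L + p$spacer_len
  mm <- matrix(FALSE, nrow = length(w), ncol = 5L)
  for (k in 1:5) {
    mm[, k] <- base_at(arm2_off + k) != unname(COMPLEMENT[base_at(6L - k)])
  }
  disallowed <- setdiff(1:5, p$allowed_arm2_mismatch_positions)
  ok_disallowed <- if (length(disallowed) > 0) {
    rowSums(mm[, disallowed, drop = FALSE]) == 0L
  } else rep(TRUE, length(w))
  n_allowed_mm <- if (length(p$allowed_arm2_mismatch_positions) > 0) {
    rowSums(mm[, p$allowed_arm2_mismatch_positions, drop = FALSE])
  } else rep(0L, length(w))

  matched <- arm_ok & (gc <= p$max_spacer_gc) & ok_disallowed &
    (n_allowed_mm <= p$max_arm_mismatches)

  first_mm <- apply(mm, 1L, function(row) {
    hit <- which(row)
    if (length(hit) == 0) 0L else hit[1]
  })
  tibble(
    matched = matched,
    arm_mismatch_position = as.integer(first_mm),
    spacer_gc_count = as.integer(gc)
  )
}

#' Enumerate every window accepted by a pattern
#'
#' Builds the exact accepted set by direct product enumeration: every arm-1
#' realisation of the template, every admissible spacer (all A/T, or one C/G
#' and the rest A/T), and every admissible arm-2 variant (the exact reverse
#' complement plus, when mismatches are tolerated, the three substitutions at
#' each allowed position). Intended as a ground-truth oracle and as the
#' sampling space for the synthetic-data generator.
#'
#' @param p A [compile_pattern()] object.
#' @param cap Maximum set size to materialise; larger patterns raise an error
#'   advising constructive sampling via [sample_accepted_site()].
#' @return Character vector of distinct accepted 18-mers.
#' @export
enumerate_accepted <- function(p, cap = 5e6) {
  stopifnot(inherits(p, "rex_pattern"))
  arm_choices <- lapply(p$arm_template, function(s) ARM_ALPHABET[[s]])
  n_arm1 <- prod(lengths(arm_choices))
  n_spacer <- admissible_spacer_count(p$spacer_len, p$max_spacer_gc)
  n_arm2 <- 1L + if (p$max_arm_mismatches > 0) {
    3L * length(p$allowed_arm2_mismatch_positions)
  } else 0L
  total <- n_arm1 * n_spacer * n_arm2
  if (total > cap) {
    abort(sprintf(
      "accepted set has %.0f members, above the cap of %.0f; use sample_accepted_site() instead.",
      total, cap
    ), class = "rex_config_error")
  }

  arm1s <- apply(expand.grid(arm_choices, stringsAsFactors = FALSE), 1L, paste0,
                 collapse = "")
  spacers <- enumerate_spacers(p$spacer_len, p$max_spacer_gc)

  arm_pairs <- unlist(lapply(arm1s, function(a1) {
    a2 <- expected_arm2(a1)
    variants <- a2
    if (p$max_arm_mismatches > 0) {
      for (pos in p$allowed_arm2_mismatch_positions) {
        ref <- substr(a2, pos, pos)
        for (b in setdiff(DNA_BASES, ref)) {
          v <- a2
          substr(v, pos, pos) <- b
          variants <- c(variants, v)
        }
      }
    }
    paste0(a1, "|", variants)
  }))

  grid <- expand.grid(pair = arm_pairs, spacer = spacers,
                      stringsAsFactors = FALSE)
  halves <- strsplit(grid$pair, "|", fixed = TRUE)
  out <- paste0(vapply(halves, `[`, "", 1L), grid$spacer,
                vapply(halves, `[`, "", 2L))
  unique(out)
}

admissible_spacer_count <- function(len, max_gc) {
  sum(vapply(0:max_gc, function(k) choose(len, k) * 2^k * 2^(len - k), 0))
}

enumerate_spacers <- function(len, max_gc) {
  at_only <- apply(
    expand.grid(rep(list(c("A", "T")), len), stringsAsFactors = FALSE),
    1L, paste0, collapse = ""
  )
  out <- at_only
  if (max_gc >= 1L) {
    shorter <- apply(
      expand.grid(rep(list(c("A", "T")), len - 1L), stringsAsFactors = FALSE),
      1L, paste0, collapse = ""
    )
    for (pos in seq_len(len)) {
      for (b in c("C", "G")) {
        out <- c(out, paste0(substr(shorter, 1L, pos - 1L), b,
                             substring(shorter, pos)))
      }
    }
  }
  if (max_gc >= 2L) {
    abort("spacer enumeration supports at most one G/C.", class = "rex_config_error")
  }
  unique(out)
}
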