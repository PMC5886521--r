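# Independent rule-check oracle for the 18-bp operator window, coded as
# three separate clauses over plain string operations (regex arm check,
# character-deletion GC count, per-position complement comparison). Kept
# deliberately apart from the package's matcher so the two can disagree.

oracle_complement <- function(b) chartr("ACGT", "TGCA", b)

oracle_clauses <- function(w) {
  arm_ok <- grepl("^[AT]TG[AT][AT]", w)
  spacer <- substr(w, 6, 13)
  gc_ok <- nchar(gsub("[AT]", "", spacer)) <= 1
  mism <- matrix(FALSE, length(w), 5)
  for (k in 1:5) {
    mism[, k] <- substr(w, 13 + k, 13 + k) !=
      oracle_complement(substr(w, 6 - k, 6 - k))
  }
  n_mm <- rowSums(mism)
  arm2_ok <- n_mm == 0 | (n_mm == 1 & (mism[, 4] | mism[, 5]))
  arm_ok & gc_ok & arm2_ok
}

random_18mers <- function(n) {
  do.call(paste0, as.data.frame(
    matrix(sample(c("A", "C", "G", "T"), n * 18, replace = TRUE), ncol = 18),
    stringsAsFactors = FALSE
  ))
}

# slow but simple reverse complement used where independence matters
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(oracle_complement(s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# a tiny synthetic bundle shared by annotation/pipeline tests
make_bundle <- function(seed = 42,
                        dir = withr::local_tempdir(.local_envir = parent.frame()),
                        genome_length = 100000, n_sites = 20, ...) {
  p <- compile_pattern("paper-union")
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  g <- gen_genome(generator_config(seed = seed, genome_length = genome_length,
                                   n_sites = n_sites, ...), p,
                  fasta_path = fa)
  gen_gff(g$truth, gff)
  list(p = p, fasta = fa, gff = gff, gen = g, dir = dir)
}
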