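# Shared fixture builders: everything is generated in code at test time.

make_records <- function(peptides, alleles = "DRB1*07:01", labels = 1L,
                         genes = "", n_flanks = "", c_flanks = "",
                         domain = "antigenic") {
  tibble::tibble(
    peptide = peptides,
    allele = rep_len(alleles, length(peptides)),
    label = rep_len(as.integer(labels), length(peptides)),
    gene = rep_len(genes, length(peptides)),
    n_flank = rep_len(n_flanks, length(peptides)),
    c_flank = rep_len(c_flanks, length(peptides)),
    domain = domain, source = "test")
}

random_peptides <- function(n, len_range = c(12L, 19L), seed = 1L) {
  lens <- len_range[1]:len_range[2]
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      L <- if (length(lens) == 1L) lens else sample(lens, 1L)
      paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

write_tsv_tmp <- function(tbl, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  readr::write_tsv(tbl, path)
  path
}

toy_pseudo <- function(alleles = "DRB1*07:01", seed = 42L) {
  withr::with_seed(seed, tibble::tibble(
    allele = alleles,
    short_seq = vapply(alleles, function(a)
      paste(sample(aa_alphabet(), 34L, TRUE), collapse = ""), character(1)),
    full_seq = vapply(alleles, function(a)
      paste(sample(aa_alphabet(), 269L, TRUE), collapse = ""), character(1))))
}

# numerical gradient of scalar-valued fn at x (vector or matrix)
num_grad <- function(fn, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# stacked one-hot + BLOSUM62 encoding via the package namespace
encode_stacked_test <- function(seq, pad_to) {
  asNamespace("mhc2epi")$encode_stacked(seq, pad_to)
}

# tiny presentation-model config used across model tests
tiny_el_config <- function(seed = 1L, epochs = 2L) {
  el_config(d_model = 8L, n_heads = 2L, d_ban = 8L, epochs = epochs,
            lr = 3e-3, seed = seed)
}
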