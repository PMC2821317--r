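# Small shared helpers. Sorting must be locale-independent so that every
# tie-break in the pipeline is reproducible bit-for-bit across machines.

# C-locale (byte order) sort / order for character vectors
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_op <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

# canonical unordered pair key for similarity lookups
pair_key <- function(a, b) {
  swap <- a > b
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "\r")
}

# translate CDS to protein with a plain codon table; internal stops become '*'
# (kept; BLOSUM62 has a '*' row so downstream scoring remains defined)
translate_cds <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  vapply(cds, function(s) {
    if (is.na(s) || nchar(s) == 0L) return("")
    n <- nchar(s) %/% 3L
    codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# strip one trailing stop codon from a CDS if present
strip_trailing_stop <- function(cds) {
  n <- nchar(cds)
  last <- substring(cds, n - 2L, n)
  is_stop <- n >= 3L & last %in% c("TAA", "TAG", "TGA")
  ifelse(is_stop, substring(cds, 1L, n - 3L), cds)
}
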