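# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# Map a DNA string to integer codes 1:4 (A,C,G,T); anything else becomes NA.
seq_to_code <- function(s) {
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt(s)]
}

code_to_seq <- function(code) {
  intToUtf8(utf8ToInt("ACGT")[code])
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic 31-bit child seed from a master seed plus arbitrary labels.
# Polynomial string hash; all arithmetic stays exact in doubles (< 2^53).
child_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483647
  as.integer((h + as.numeric(master) %% 2147483647 * 31) %% 2147483647 + 1)
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name))
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  if (integer && x != floor(x))
    stop(sprintf("'%s' must be an integer", name))
  invisible(x)
}

# rbinom(1, size, p) that tolerates size > .Machine$integer.max by chunking.
rbinom_big <- function(size, prob) {
  if (prob <= 0 || size <= 0) return(0)
  chunk <- 2^30
  n_full <- floor(size / chunk)
  rest <- size - n_full * chunk
  tot <- 0
  if (n_full > 0) tot <- sum(stats::rbinom(n_full, chunk, prob))
  if (rest > 0) tot <- tot + stats::rbinom(1L, rest, prob)
  tot
}
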