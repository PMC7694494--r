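#' @keywords internal
"_PACKAGE"

# DNA helpers on plain character data. Sequences are uppercase strings over
# {A,C,G,T,N}; alignments additionally use '-'. Internal coordinates are
# 0-based half-open; anything written for humans is 1-based inclusive.

BASES <- c("A", "C", "G", "T")

comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(s) {
  # reverse complement of a string (not a character vector)
  paste(rev(comp_chars(strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
}

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_to_seq <- function(v) paste(v, collapse = "")

#' Round half away from zero to a fixed number of decimals
#'
#' Base `round()` rounds half to even; printed genome summaries follow the
#' usual half-up convention instead (38.25 -> 38.3).
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# circular index: map 0-based position onto [0, n)
cpos <- function(i, n) ((i %% n) + n) %% n

# GC fraction of a character vector (A/C/G/T denominator; N ignored)
gc_fraction <- function(v) {
  acgt <- sum(v %in% BASES)
  if (acgt == 0) return(NA_real_)
  sum(v == "G" | v == "C") / acgt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
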