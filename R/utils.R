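# Internal helpers shared across modules.

# Classed conditions so the CLI can map error families onto exit codes
# (format errors -> 2, contract violations -> 3).
stop_format <- function(...) {
  stop(structure(
    class = c("mb_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_contract <- function(...) {
  stop(structure(
    class = c("mb_contract_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the \code{\{A,C,G,T,N\}} alphabet.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Count of a given character in each string.
count_char <- function(x, ch) {
  nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE))
}

# All substrings of length k of a single sequence (character scalar).
substrings_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}
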