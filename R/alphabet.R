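#' @keywords internal
"_PACKAGE"

# Canonical 20-state amino-acid order used throughout (PAML dat order).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHAR <- "-"
UNKNOWN_CHAR <- "X"

aa_index <- function(x) match(x, AA20)

is_missing_state <- function(x) x == GAP_CHAR | x == UNKNOWN_CHAR

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
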