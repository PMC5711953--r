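# Independent oracle for binomial upper tails: weighted enumeration over
# all 2^n success/failure sequences (no binomial coefficients, no
# distribution functions).
binom_tail_oracle <- function(n, k, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  total <- 0
  for (code in 0:(2^n - 1)) {
    s <- sum(bitwAnd(code, bitwShiftL(1, 0:(n - 1))) != 0)
    if (s >= k) total <- total + p^s * (1 - p)^(n - s)
  }
  total
}

# Tiny 5-taxon toy system used by several matrix tests:
# tree (((A,B),C),(D,E)); reference A.
toy_tree <- function() ape::read.tree(text = "(((A,B),C),(D,E));")

toy_matrix <- function(patterns) {
  taxa <- c("A", "B", "C", "D", "E")
  calls <- matrix("-", length(taxa), length(patterns),
                  dimnames = list(taxa, names(patterns)))
  for (l in names(patterns)) {
    p <- patterns[[l]]
    calls[p$pres, l] <- "+"
    if (!is.null(p$miss)) calls[p$miss, l] <- "?"
  }
  marker_matrix(calls)
}
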