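# Independent brute-force oracles used to validate the implementation.

# Maximal homopolymer runs by explicit per-start extension: every start
# position is tested for extendability and left-maximality, independent of
# the rle-based scanner.
oracleRuns <- function(sequence, minRunLength, alphabet = polyXnet::AA_STANDARD) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(ch)
  out <- list()
  for (i in seq_len(L)) {
    if (i > 1 && ch[i - 1] == ch[i]) next        # not left-maximal
    j <- i
    while (j < L && ch[j + 1] == ch[i]) j <- j + 1
    if (j - i + 1 >= minRunLength && ch[i] %in% alphabet)
      out[[length(out) + 1]] <- data.frame(
        residue = ch[i], start = i, end = j, length = j - i + 1,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(residue = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

randomSequence <- function(len, alphabet = c(polyXnet::AA_STANDARD, "X", "*")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Re-classify every edge of an interactome by direct membership lookup.
oracleClassify <- function(edgeDf, group) {
  in1 <- edgeDf[[1]] %in% group
  in2 <- edgeDf[[2]] %in% group
  list(type_a = sum(in1 & in2), type_b = sum(xor(in1, in2)),
       incident = sum(in1 | in2))
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# size-n draws from N items of which the first K carry the feature.
oracleHyperTail <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Benjamini-Hochberg step-up from the definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Interval overlap by materializing both position sets.
oracleOverlap <- function(a1, a2, b1, b2) length(intersect(seq(a1, a2), seq(b1, b2)))

# Closed-form Yates chi-squared for a 2x2 table of (a1,b1) vs (a2,b2).
oracleYates <- function(a1, b1, a2, b2) {
  N <- a1 + b1 + a2 + b2
  num <- max(0, abs(a1 * b2 - b1 * a2) - N / 2)
  N * num^2 / ((a1 + b1) * (a2 + b2) * (a1 + a2) * (b1 + b2))
}

# small two-column edge fixture used across interactome tests:
# group {A,B,C}; edges A-B (type a), A-X, B-Y, C-Z (type b), X-Y (excluded)
toyInteractome <- function() {
  makeInteractome(data.frame(a = c("A", "A", "B", "C", "X"),
                             b = c("B", "X", "Y", "Z", "Y"),
                             stringsAsFactors = FALSE))
}
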