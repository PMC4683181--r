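# Internal helpers: deterministic sub-seed derivation, pair-index codecs for
# the planted-partition sampler, and stable TSV output.

# Derive a reproducible 31-bit sub-seed from a master seed and up to two
# integer tags (e.g. residue code, replicate index).  Pure arithmetic on
# doubles; all intermediates stay < 2^53 so the result is exact.
deriveSeed <- function(seed, tag1 = 0L, tag2 = 0L) {
  m <- 2147483629
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(tag1) * 16807 + 11) %% m
  s <- (s * 69621 + as.numeric(tag2) * 30269 + 17) %% m
  as.integer(s)
}

# Integer code of a group tag (residue letter or arbitrary label).
tagCode <- function(tag) {
  if (is.numeric(tag)) return(as.integer(tag))
  sum(utf8ToInt(as.character(tag)[1]) * seq_len(nchar(as.character(tag)[1])))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Colexicographic codec for unordered pairs (i < j) over 1..n:
#   index(i, j) = choose(j - 1, 2) + i,  index in 1..choose(n, 2).
pairIndexEncode <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (hi - 1) * (hi - 2) / 2 + lo
}

pairIndexDecode <- function(k) {
  # smallest j with choose(j-1, 2) < k  <=>  j = floor((3+sqrt(8k-7))/2)
  j <- floor((3 + sqrt(8 * k - 7)) / 2)
  # guard against floating-point boundary error
  adj <- (j - 1) * (j - 2) / 2 >= k
  j[adj] <- j[adj] - 1
  adj2 <- j * (j - 1) / 2 < k
  j[adj2] <- j[adj2] + 1
  i <- k - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

# Stable TSV writer used by every pipeline artifact (byte-identical across
# runs for identical inputs).
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

sampleSem <- function(x) sd(x) / sqrt(length(x))
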