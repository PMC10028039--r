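# Independent brute-force oracles used to check the package implementations.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_rc <- function(x)
  paste(ORACLE_COMP[rev(strsplit(x, "")[[1]])], collapse = "")

# naive O(n*m) double-loop duplex scan with palindrome dedup
oracle_scan <- function(seq, motif) {
  sc <- strsplit(seq, "")[[1]]
  match_at <- function(pat) {
    pc <- strsplit(pat, "")[[1]]
    w <- length(pc)
    if (length(sc) < w) return(integer(0))
    hits <- integer(0)
    for (i in seq_len(length(sc) - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!(sc[i + j - 1L] %in% ORACLE_IUPAC[[pc[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
    hits
  }
  fwd <- match_at(motif)
  rev <- setdiff(match_at(oracle_rc(motif)), fwd)
  data.frame(start = c(fwd, rev) - 1L,
             orientation = rep(c("+", "-"), c(length(fwd), length(rev))))[
               order(c(fwd, rev)), , drop = FALSE]
}

# exact hypergeometric upper tail by explicit summation of binomial products
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

random_motif <- function(len, alphabet = c("A", "C", "G", "T", "W", "N")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_backbone <- function() {
  n1 <- sample(2:8, 1)
  n2 <- sample(1:n1, 1)
  hairpin_polyamide(sample(c("Py", "Im", "Beta"), n1, replace = TRUE),
                    sample(c("Py", "Im", "Beta"), n2, replace = TRUE),
                    cap = if (runif(1) < 0.5) "AcCap" else NULL,
                    tail = if (runif(1) < 0.5) "IndoleSecoCBI" else NULL)
}
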