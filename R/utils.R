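# Internal helpers shared across modules.

DNA <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Phred+33 helpers. Quality strings are ASCII; scores are numeric Phred.
phred_to_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)
char_to_phred <- function(s) utf8ToInt(s) - 33L

# Haldane mapping function (no interference): rf -> cM and back.
haldane_cM <- function(r) -50 * log(1 - 2 * pmin(r, 0.499999))
inv_haldane <- function(d) 0.5 * (1 - exp(-2 * d / 100))

# Deterministic per-stage child seed derived from one global seed; kept
# below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) %% 65536 * 30269 + h * 7919 + 17) %% 2147483629)
}

# One-hot encoding of equal-length sequences, used for blockwise pairwise
# Hamming distances via matrix multiplication.
seq_onehot <- function(seqs) {
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  oh <- matrix(0, nrow = length(seqs), ncol = 4L * L)
  for (i in seq_along(DNA)) {
    oh[, seq.int(i, by = 4L, length.out = L)] <- (m == DNA[i]) * 1
  }
  oh
}

# All-pairs Hamming distances <= max_mm among equal-length sequences,
# returned as an edge list (i, j). Blockwise to bound memory.
hamming_pairs <- function(seqs, max_mm, block = 2000L) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  L <- nchar(seqs[1])
  oh <- seq_onehot(seqs)
  out <- list()
  starts <- seq.int(1L, n, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    sim <- oh[s:e, , drop = FALSE] %*% t(oh)
    d <- L - sim
    hit <- which(d <= max_mm, arr.ind = TRUE)
    hit[, 1] <- hit[, 1] + s - 1L
    out[[length(out) + 1L]] <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
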