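# Independent oracles used by the dual-route tests.  These deliberately do
# not share code (or algorithmic structure, where feasible) with the
# package implementations they check.

# --- local alignment: plain R dynamic programme over explicit gap states ---
# gap of length k costs open + k * extend; returns the optimal local score.
sw_affine_oracle <- function(a, b, mat, open = 11, extend = 1) {
  m <- nchar(a); n <- nchar(b)
  if (m == 0 || n == 0) return(0)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

random_peptide <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), len, replace = TRUE), collapse = "")
}

random_dna_str <- function(len, alphabet = c("A","C","G","T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- inverted repeats: brute-force enumeration over all
# (arm1_start, spacer, arm_len) triples, with the maximality and
# containment rules applied explicitly ---
comp_vec <- function(v) c(A = "T", C = "G", G = "C", T = "A", N = "?")[v]

ir_oracle <- function(seq, min_arm, max_gap, max_mismatch,
                      semantics = "per_arm") {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  cs <- unname(comp_vec(s))   # "?" for N: never equal to a base
  mism_count <- function(a1s, k, g) {
    # Hamming(arm1, revcomp(arm2)): position p of arm1 pairs with
    # position (k-1-p) of arm2
    i1 <- (a1s + 1):(a1s + k)
    i2 <- (a1s + 2 * k + g):(a1s + k + g + 1)
    sum(s[i1] != cs[i2])
  }
  cand <- list()
  for (a1s in 0:(L - 1)) {
    for (g in 0:max_gap) {
      for (k in 1:L) {
        a2e <- a1s + 2 * k + g
        if (a2e > L) break
        mm <- mism_count(a1s, k, g)
        if (mm > max_mismatch) next
        # maximality: symmetric outward extension must be impossible
        ext_ok <- a1s - 1 >= 0 && a2e + 1 <= L &&
          mm + (s[a1s] != cs[a2e + 1]) <= max_mismatch
        if (ext_ok) next
        len_ok <- if (semantics == "per_arm") k >= min_arm else
          2 * k + g >= min_arm
        if (!len_ok) next
        cand[[length(cand) + 1L]] <- c(a1s = a1s, k = k, g = g, mm = mm)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(arm1_start = integer(0), arm1_end = integer(0),
                      arm2_start = integer(0), arm2_end = integer(0),
                      arm_len = integer(0), spacer_len = integer(0),
                      mismatches = integer(0)))
  }
  d <- as.data.frame(do.call(rbind, cand))
  # containment suppression: drop repeats wholly contained (both arms)
  # in a longer repeat with equal spacer
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      if (i == j || d$g[j] != d$g[i] || d$k[j] <= d$k[i]) next
      a1_in <- d$a1s[i] >= d$a1s[j] &&
        d$a1s[i] + d$k[i] <= d$a1s[j] + d$k[j]
      a2s_i <- d$a1s[i] + d$k[i] + d$g[i]
      a2s_j <- d$a1s[j] + d$k[j] + d$g[j]
      a2_in <- a2s_i >= a2s_j && a2s_i + d$k[i] <= a2s_j + d$k[j]
      if (a1_in && a2_in) { keep[i] <- FALSE; break }
    }
  }
  d <- d[keep, , drop = FALSE]
  out <- data.frame(arm1_start = d$a1s, arm1_end = d$a1s + d$k,
                    arm2_start = d$a1s + d$k + d$g,
                    arm2_end = d$a1s + 2 * d$k + d$g,
                    arm_len = d$k, spacer_len = d$g, mismatches = d$mm)
  out <- out[order(out$arm1_start, -out$arm_len, out$spacer_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}
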