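# Independent oracles kept deliberately separate from the package's code
# paths: a plain affine-gap Needleman-Wunsch, a double-loop Bray-Curtis,
# and a brute-force exhaustive Mantel enumeration.

# Affine-gap global alignment (penalty for a gap of length k =
# open + k * extend, matching the package's alignment parameterization).
# Returns the two gapped alignment strings.
nw_align_oracle <- function(a, b, submat, open = 10, extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (B consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  # traceback; ties prefer M (diagonal) > X (up) > Y (left)
  pick <- function(scores) which(scores >= max(scores) - 1e-9)[1]
  ga <- character(0); gb <- character(0)
  i <- n + 1; j <- m + 1
  state <- pick(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1) {
      s <- submat[A[i - 1], B[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      stopifnot(abs(M[i, j] - (max(prev) + s)) < 1e-9)
      ga <- c(A[i - 1], ga); gb <- c(B[j - 1], gb)
      i <- i - 1; j <- j - 1
      state <- pick(prev)
    } else if (state == 2) {
      ga <- c(A[i - 1], ga); gb <- c("-", gb)
      prev <- c(M[i - 1, j] - open - extend, X[i - 1, j] - extend, NEG)
      i <- i - 1
      state <- pick(prev)
    } else {
      ga <- c("-", ga); gb <- c(B[j - 1], gb)
      prev <- c(M[i, j - 1] - open - extend, NEG, Y[i, j - 1] - extend)
      j <- j - 1
      state <- pick(prev)
    }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""))
}

# Residue of `query` in the alignment column holding reference position
# `site`, via the oracle alignment (query first, reference second).
oracle_residue_at <- function(query, ref, site, submat) {
  al <- nw_align_oracle(query, ref, submat)
  qa <- strsplit(al$a, "")[[1]]
  ra <- strsplit(al$b, "")[[1]]
  pos <- cumsum(ra != "-")
  col <- match(site, pos)
  if (is.na(col) || ra[col] == "-") return(NA_character_)
  qa[col]
}

# Double-loop Bray-Curtis from the definition.
bray_oracle <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      denom <- sum(mat[i, ] + mat[j, ])
      d[i, j] <- if (denom == 0) 0 else sum(abs(mat[i, ] - mat[j, ])) / denom
    }
  }
  d
}

# All permutations of 1..n, built by a different recursion than the
# package's enumerator (insertion construction).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- perms_oracle(n - 1)
  out <- list()
  for (p in smaller) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exhaustive Mantel p-value from the definition.
mantel_exhaustive_oracle <- function(dx, dy) {
  xv <- as.vector(dx)
  M <- as.matrix(dy)
  lt <- lower.tri(M)
  r_obs <- cor(xv, M[lt])
  ps <- perms_oracle(attr(dx, "Size"))
  rs <- vapply(ps, function(p) cor(xv, M[p, p][lt]), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Test-local BLOSUM62 (via Biostrings data, shared constant, not a code path)
get_blosum62_test <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Small deterministic distance fixtures
rand_dist <- function(n, seed) {
  set.seed(seed)
  d <- dist(matrix(rnorm(n * 3), n))
  attr(d, "Labels") <- paste0("S", seq_len(n))
  d
}
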