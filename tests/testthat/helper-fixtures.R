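# Shared fixtures and independent oracles for the test suite.

rand_image <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}

# Circular (periodic) shift: y(i, j) = x(i - dr, j - dc) mod size.
circ_shift <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  x[((seq_len(nr) - 1L - dr) %% nr) + 1L,
    ((seq_len(nc) - 1L - dc) %% nc) + 1L, drop = FALSE]
}

# Wrap a plain atom matrix as a dictionary object.
as_dict <- function(atoms) {
  structure(list(atoms = atoms, cluster_offsets = 0L, cluster_ids = 1L,
                 patch_size = as.integer(round(sqrt(nrow(atoms))))),
            class = "nss_dictionary")
}

random_orthonormal_dictionary <- function(n, seed) {
  set.seed(seed)
  as_dict(qr.Q(qr(matrix(rnorm(n * n), n, n))))
}

# --- brute-force focus-measure oracle (loops, coded independently) ---

reflect1 <- function(i, n) {
  m <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n)
  if (m < n) m + 1 else 2 * n - m
}

brute_ml <- function(b, step = 1) {
  nr <- nrow(b); nc <- ncol(b)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <-
        abs(2 * b[i, j] - b[reflect1(i - step, nr), j] -
              b[reflect1(i + step, nr), j]) +
        abs(2 * b[i, j] - b[i, reflect1(j - step, nc)] -
              b[i, reflect1(j + step, nc)])
    }
  }
  out
}

brute_sml <- function(ml, p = 1, q = 1) {
  nr <- nrow(ml); nc <- ncol(ml)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in -p:p) {
        for (b2 in -q:q) {
          acc <- acc + ml[reflect1(i + a, nr), reflect1(j + b2, nc)]^2
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

brute_sml_max_fuse <- function(ba, bb, step = 1, p = 1, q = 1) {
  sa <- brute_sml(brute_ml(ba, step), p, q)
  sb <- brute_sml(brute_ml(bb, step), p, q)
  out <- bb
  out[sa >= sb] <- ba[sa >= sb]
  out
}

# Binned Shannon entropy in bits (oracle for the MI identity).
brute_entropy <- function(x, bins = 256) {
  b <- pmin(pmax(floor(x * bins), 0), bins - 1)
  p <- tabulate(b + 1, nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}
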