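# Compact dictionary learning by joint patch clustering and per-cluster
# PCA. Patches from both source low-pass bands are pooled, clustered
# with k-means (k-means++ seeding, Lloyd iterations), and each cluster
# contributes the smallest set of leading eigenvectors holding at least
# a fraction `delta` of its variance. Sub-dictionaries are concatenated
# into the aggregate dictionary Phi.

patch_grid <- function(dim, patch_size, stride) {
  pr <- seq.int(1L, dim[1] - patch_size + 1L, by = stride)
  pc <- seq.int(1L, dim[2] - patch_size + 1L, by = stride)
  # row-major enumeration: sweep columns within each row block
  cbind(row = rep(pr, each = length(pc)), col = rep(pc, times = length(pr)))
}

# Linear-index matrix (patch_size^2 x T); patches vectorized column-major.
patch_indices <- function(dim, patch_size, stride) {
  pos <- patch_grid(dim, patch_size, stride)
  di <- rep(0:(patch_size - 1L), times = patch_size)
  dj <- rep(0:(patch_size - 1L), each = patch_size)
  outer(di + dj * dim[1], pos[, 1L] + (pos[, 2L] - 1L) * dim[1], `+`)
}

#' Extract mean-removed sliding-window patches
#'
#' Slides a `patch_size` x `patch_size` window over the band with the
#' given stride, top-left to bottom-right, vectorizes each patch
#' column-major, removes its mean and stores the mean separately.
#'
#' @param band Numeric matrix.
#' @param patch_size Patch side length in pixels.
#' @param stride Step between window origins (>= 1).
#' @return An `nss_patch_set`: list with `vectors` (`patch_size^2 x T`
#'   zero-mean columns), `means` (length `T`), `positions` (`T x 2`
#'   1-based top-left coordinates), `patch_size`, `stride`, `dim`.
#' @export
extract_patches <- function(band, patch_size, stride = 1L) {
  stopifnot(is.matrix(band))
  if (patch_size > min(dim(band)))
    stop_input("patch_size (", patch_size, ") exceeds band size (",
               paste(dim(band), collapse = "x"), ")")
  if (stride < 1L) stop_config("stride must be >= 1")
  li <- patch_indices(dim(band), patch_size, stride)
  V <- matrix(band[li], nrow = patch_size^2)
  means <- colMeans(V)
  V <- sweep(V, 2L, means)
  structure(list(vectors = V, means = means,
                 positions = patch_grid(dim(band), patch_size, stride),
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 dim = dim(band)),
            class = "nss_patch_set")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1L], ])^2)
  for (i in seq_len(k - 1L)) {
    if (sum(d2) <= 0) {
      centers[i + 1L] <- sample.int(n, 1L)
    } else {
      centers[i + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[i + 1L], ])^2))
  }
  X[centers, , drop = FALSE]
}

# Lloyd iterations; empty clusters are dropped (with a warning) rather
# than reseeded, so the result is deterministic given the initial centers.
lloyd_cluster <- function(X, C, max_iter = 50L) {
  xs2 <- rowSums(X^2)
  assign_prev <- NULL
  dropped <- FALSE
  for (it in seq_len(max_iter)) {
    D <- outer(xs2, rowSums(C^2), `+`) - 2 * X %*% t(C)
    a <- max.col(-D, ties.method = "first")
    sizes <- tabulate(a, nbins = nrow(C))
    if (any(sizes == 0L)) {
      keep <- sizes > 0L
      C <- C[keep, , drop = FALSE]
      a <- match(a, which(keep))
      sizes <- sizes[keep]
      dropped <- TRUE
    }
    if (!is.null(assign_prev) && length(a) == length(assign_prev) &&
        all(a == assign_prev)) break
    assign_prev <- a
    C <- rowsum(X, a) / sizes
  }
  if (dropped) warning("empty cluster(s) dropped during k-means")
  a
}

#' Joint clustering of pooled patches from two sources
#'
#' Pools the mean-removed patch vectors of both sources and partitions
#' them into `k` clusters with k-means (k-means++ seeding, Lloyd
#' updates). Deterministic for a fixed seed; clusters that empty out
#' are dropped with a warning.
#'
#' @param patches_a,patches_b `nss_patch_set` objects with equal patch size.
#' @param k Number of clusters (>= 1, at most the pooled patch count).
#' @param seed Integer RNG seed for the initialization.
#' @return Integer cluster label per pooled patch (columns of
#'   `patches_a` first, then `patches_b`).
#' @export
joint_cluster <- function(patches_a, patches_b, k, seed = 0L) {
  stopifnot(inherits(patches_a, "nss_patch_set"),
            inherits(patches_b, "nss_patch_set"))
  X <- t(cbind(patches_a$vectors, patches_b$vectors))
  if (k < 1L) stop_config("k must be >= 1")
  if (k > nrow(X))
    stop_input("k (", k, ") exceeds pooled patch count (", nrow(X), ")")
  with_seed(seed, {
    C <- kmeanspp_init(X, k)
    lloyd_cluster(X, C)
  })
}

# Deterministic sign convention: first component of nontrivial magnitude
# is positive.
fix_eigenvector_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    nz <- which(abs(U[, j]) > 1e-8)
    if (length(nz) > 0L && U[nz[1L], j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Per-cluster PCA sub-dictionary
#'
#' Eigendecomposes the cluster's (uncentered) second-moment matrix --
#' patch vectors are already zero-mean -- and keeps the smallest number
#' `p` of leading eigenvectors whose eigenvalue mass fraction reaches
#' `delta`. With `delta = 1` the full rank is kept. An all-zero cluster
#' yields an empty sub-dictionary flagged degenerate.
#'
#' @param cluster_vectors Matrix with one zero-mean patch vector per column.
#' @param delta Retained-variance fraction in (0, 1].
#' @param cluster_id Optional integer identifier.
#' @return An `nss_subdict`: list with `atoms` (orthonormal columns),
#'   `eigenvalues` (descending, length `p`), `cluster_id`, `degenerate`.
#' @export
pca_subdictionary <- function(cluster_vectors, delta = 0.95, cluster_id = NA_integer_) {
  stopifnot(is.matrix(cluster_vectors), ncol(cluster_vectors) >= 1L)
  if (delta <= 0 || delta > 1) stop_config("delta must be in (0, 1]")
  n <- nrow(cluster_vectors)
  m <- ncol(cluster_vectors)
  cv <- tcrossprod(cluster_vectors) / m
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  tot <- sum(lam)
  if (tot <= n * 1e-14) {
    return(structure(list(atoms = matrix(0, n, 0L), eigenvalues = numeric(0),
                          cluster_id = cluster_id, degenerate = TRUE),
                     class = "nss_subdict"))
  }
  if (delta >= 1) {
    p <- sum(lam > lam[1L] * 1e-12)
  } else {
    p <- which(cumsum(lam) / tot >= delta)[1L]
  }
  atoms <- fix_eigenvector_signs(e$vectors[, seq_len(p), drop = FALSE])
  structure(list(atoms = atoms, eigenvalues = lam[seq_len(p)],
                 cluster_id = cluster_id, degenerate = FALSE),
            class = "nss_subdict")
}

#' Aggregate dictionary from sub-dictionaries
#'
#' Concatenates the atoms of all non-empty sub-dictionaries, in order,
#' into the dictionary matrix `Phi` and records where each cluster's
#' atoms start.
#'
#' @param subdicts List of `nss_subdict` objects.
#' @param patch_size Optional patch side length to record.
#' @return An `nss_dictionary`: list with `atoms` (unit-norm columns),
#'   `cluster_offsets` (0-based start index of each sub-dictionary),
#'   `cluster_ids`, `patch_size`.
#' @export
build_dictionary <- function(subdicts, patch_size = NULL) {
  stopifnot(length(subdicts) >= 1L)
  keep <- vapply(subdicts, function(s) ncol(s$atoms) > 0L, logical(1))
  if (!any(keep)) stop_input("all sub-dictionaries are empty")
  subdicts <- subdicts[keep]
  sizes <- vapply(subdicts, function(s) ncol(s$atoms), integer(1))
  atoms <- do.call(cbind, lapply(subdicts, `[[`, "atoms"))
  structure(list(atoms = atoms,
                 cluster_offsets = c(0L, cumsum(sizes))[seq_along(sizes)],
                 cluster_ids = vapply(subdicts,
                                      function(s) as.integer(s$cluster_id),
                                      integer(1)),
                 patch_size = patch_size %||%
                   as.integer(round(sqrt(nrow(atoms))))),
            class = "nss_dictionary")
}

#' @export
print.nss_dictionary <- function(x, ...) {
  cat(sprintf("<nss_dictionary: %d atoms of dim %d, %d clusters>\n",
              ncol(x$atoms), nrow(x$atoms), length(x$cluster_offsets)))
  invisible(x)
}

#' Learn the fusion dictionary from a pair of low-pass bands
#'
#' Runs the full dictionary pipeline on one image pair: extract patches
#' from both bands, pool and cluster them jointly, build one PCA
#' sub-dictionary per cluster, and concatenate. When every cluster is
#' degenerate (e.g. two constant bands), a minimal one-atom fallback
#' dictionary is returned so that downstream coding, whose codes are
#' then all zero, stays well defined.
#'
#' @param l_a,l_b Low-pass band matrices of equal size.
#' @param cfg An [fusion_config()] (uses `patch_size`, `stride`,
#'   `n_clusters`, `delta`, `seed`).
#' @return An `nss_dictionary`.
#' @export
learn_dictionary <- function(l_a, l_b, cfg = fusion_config()) {
  stopifnot(all(dim(l_a) == dim(l_b)))
  pa <- extract_patches(l_a, cfg$patch_size, cfg$stride)
  pb <- extract_patches(l_b, cfg$patch_size, cfg$stride)
  pooled <- ncol(pa$vectors) + ncol(pb$vectors)
  k <- min(cfg$n_clusters, pooled)
  cl <- joint_cluster(pa, pb, k, cfg$seed)
  X <- cbind(pa$vectors, pb$vectors)
  ids <- sort(unique(cl))
  subdicts <- lapply(ids, function(c)
    pca_subdictionary(X[, cl == c, drop = FALSE], cfg$delta, cluster_id = c))
  nonempty <- vapply(subdicts, function(s) ncol(s$atoms) > 0L, logical(1))
  if (!any(nonempty)) {
    atom <- matrix(0, cfg$patch_size^2, 1L)
    atom[1L, 1L] <- 1
    return(structure(list(atoms = atom, cluster_offsets = 0L,
                          cluster_ids = NA_integer_,
                          patch_size = as.integer(cfg$patch_size)),
                     class = "nss_dictionary"))
  }
  build_dictionary(subdicts, patch_size = cfg$patch_size)
}

#' Save / load a dictionary as plain text
#'
#' The format is a small header (`patch_size`, atom dimension, atom
#' count, cluster offsets) followed by the atom matrix, one row per
#' line, whitespace-separated.
#'
#' @param dict An `nss_dictionary`.
#' @param path File path.
#' @return `save_dictionary` returns `path` invisibly; `load_dictionary`
#'   returns an `nss_dictionary`.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "nss_dictionary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("nss_dictionary", 1L),
    paste("patch_size", dict$patch_size),
    paste("dim", nrow(dict$atoms)),
    paste("atoms", ncol(dict$atoms)),
    paste("offsets", paste(dict$cluster_offsets, collapse = " "))
  ), con)
  utils::write.table(format(dict$atoms, digits = 17, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop_input("dictionary file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 5L || !startsWith(lines[1L], "nss_dictionary"))
    stop_input("not a dictionary file: ", path)
  hdr <- function(i) strsplit(lines[i], " +")[[1L]]
  patch_size <- as.integer(hdr(2L)[2L])
  n <- as.integer(hdr(3L)[2L])
  k <- as.integer(hdr(4L)[2L])
  offsets <- as.integer(hdr(5L)[-1L])
  vals <- scan(text = lines[-(1:5)], quiet = TRUE)
  atoms <- matrix(vals, nrow = n, ncol = k, byrow = TRUE)
  structure(list(atoms = atoms, cluster_offsets = offsets,
                 cluster_ids = rep(NA_integer_, length(offsets)),
                 patch_size = patch_size),
            class = "nss_dictionary")
}
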