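#' Encode a simple undirected graph in graph6 format
#'
#' graph6 is a compact ASCII encoding of simple undirected graphs: one size
#' byte (n + 63 for n <= 62) followed by the upper-triangle adjacency bits in
#' column-major order, packed into 6-bit chunks offset by 63.
#'
#' @param adj square 0/1 (or logical) adjacency matrix of a simple undirected
#'   graph with at most 62 nodes; the diagonal is ignored.
#' @return a single graph6 string.
#' @seealso [decode_graph6()], [canonical_topology()]
#' @export
#' @examples
#' encode_graph6(matrix(1, 3, 3) - diag(3))  # K3 -> "Bw"
encode_graph6 <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  stopifnot(n == ncol(adj), n >= 1L, n <= 62L)
  bits <- integer(0)
  if (n >= 2L) {
    bits <- unlist(lapply(2L:n, function(j) as.integer(adj[seq_len(j - 1L), j] != 0)),
                   use.names = FALSE)
  }
  npad <- (6L - length(bits) %% 6L) %% 6L
  bits <- c(bits, integer(npad))
  vals <- if (length(bits)) {
    colSums(matrix(bits, nrow = 6L) * c(32L, 16L, 8L, 4L, 2L, 1L))
  } else integer(0)
  rawToChar(as.raw(c(n + 63L, vals + 63L)))
}

#' Decode a graph6 string to an adjacency matrix
#'
#' @param s a graph6 string (ASCII, no header line).
#' @return a symmetric 0/1 adjacency matrix.
#' @export
decode_graph6 <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  vals <- as.integer(charToRaw(s)) - 63L
  if (any(vals < 0L | vals > 63L)) stop("malformed graph6 string: byte out of range")
  n <- vals[1L]
  if (n > 62L) stop("graph6 strings for n > 62 are not supported")
  nbits <- (n * (n - 1L)) %/% 2L
  body <- vals[-1L]
  if (length(body) != ceiling(nbits / 6)) stop("malformed graph6 string: wrong length")
  bits <- integer(0)
  if (length(body)) {
    bits <- as.vector(vapply(body, function(v) {
      as.integer(bitwAnd(v, c(32L, 16L, 8L, 4L, 2L, 1L)) > 0L)
    }, integer(6L)))
  }
  adj <- matrix(0L, n, n)
  idx <- 1L
  if (n >= 2L) {
    for (j in 2L:n) {
      adj[seq_len(j - 1L), j] <- bits[idx:(idx + j - 2L)]
      idx <- idx + j - 1L
    }
  }
  adj + t(adj)
}

# permutation table cache, keyed by k
.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(k) {
  key <- as.character(k)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- if (k == 1L) matrix(1L, 1L, 1L) else {
    sub <- .permutations(k - 1L)
    do.call(rbind, lapply(seq_len(k), function(i) {
      rest <- seq_len(k)[-i]
      cbind(i, matrix(rest[sub], nrow(sub)))
    }))
  }
  storage.mode(perms) <- "integer"
  .perm_cache[[key]] <- perms
  perms
}

# canonical form cache: packed adjacency bit key -> canonical graph6
.canon_cache <- new.env(parent = emptyenv(), hash = TRUE)
.ut_cache <- new.env(parent = emptyenv())

#' Canonical graph6 label of a small graph
#'
#' Computes a canonical form by exhaustive search over all k! vertex orderings,
#' selecting the lexicographically maximal upper-triangle bit string, and
#' returns its graph6 encoding. Isomorphic graphs map to identical strings.
#' Intended for the motif sizes used here (k <= 6, at most 720 orderings);
#' refuses k > 8.
#'
#' @param adj adjacency matrix of a simple undirected graph, k <= 8 nodes.
#' @return canonical graph6 string.
#' @export
canonical_topology <- function(adj) {
  adj <- as.matrix(adj) != 0
  k <- nrow(adj)
  stopifnot(k == ncol(adj), k >= 1L)
  if (k > 8L) stop("canonical_topology supports at most 8 nodes")
  kk <- as.character(k)
  ut <- .ut_cache[[kk]]
  if (is.null(ut)) {
    ut <- list(idx = which(upper.tri(matrix(0, k, k))),
               w = 2^(rev(seq_len(k * (k - 1L) / 2L)) - 1L))
    .ut_cache[[kk]] <- ut
  }
  key <- paste0(kk, "_", sum(ut$w[adj[ut$idx]]))
  hit <- .canon_cache[[key]]
  if (!is.null(hit)) return(hit)
  perms <- .permutations(k)
  best <- -1
  best_adj <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    b <- adj[p, p, drop = FALSE]
    v <- sum(ut$w[b[ut$idx]])  # first bit most significant
    if (v > best) {
      best <- v
      best_adj <- b
    }
  }
  out <- encode_graph6(best_adj * 1L)
  .canon_cache[[key]] <- out
  out
}
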