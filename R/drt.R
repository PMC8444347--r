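#' Build the distinct row table (DRT) for a spin sector
#'
#' The distinct row table is the compressed graph (Shavitt graph) whose
#' leaf-to-root paths are exactly the CSFs of a sector. Nodes at orbital
#' level `k` are Paldus rows `(a, b, c)` with `a` doubly occupied orbital
#' count, `b = 2 S_k`, and `c = k - a - b`; arcs between consecutive levels
#' carry step values. Per-node subtree counts give an O(n) bijection
#' between lexicographic indices and CSFs.
#'
#' @param space A [spin_space()].
#' @return An object of class `"drt"` with fields `space`, `dim` (number of
#'   CSFs), `counts` (per-level matrices of path counts from a node to the
#'   sector head) and an internal cache environment.
#' @examples
#' d <- build_drt(spin_space(6, 6, 0))
#' d$dim  # 175
#' @export
build_drt <- function(space) {
  assert_spin_space(space)
  n <- space$n_orbitals
  N <- space$n_electrons
  b_final <- space$twice_S
  a_final <- (N - b_final) %/% 2L
  a_max <- a_final
  b_max <- min(N, n)
  # counts[[k + 1]][a + 1, b + 1] = number of valid step continuations from
  # node (a, b) at level k up to the head (a_final, b_final) at level n.
  counts <- vector("list", n + 1L)
  for (k in 0:n) counts[[k + 1L]] <- matrix(0, a_max + 1L, b_max + 1L)
  if (b_final <= b_max) counts[[n + 1L]][a_final + 1L, b_final + 1L] <- 1
  for (k in (n - 1L):0) {
    cur <- counts[[k + 1L]]
    nxt <- counts[[k + 2L]]
    for (a in 0:a_max) {
      for (b in 0:b_max) {
        tot <- nxt[a + 1L, b + 1L]                                    # step 0
        if (b + 1L <= b_max) tot <- tot + nxt[a + 1L, b + 2L]         # step u
        if (b >= 1L && a + 1L <= a_max) tot <- tot + nxt[a + 2L, b]   # step d
        if (a + 1L <= a_max) tot <- tot + nxt[a + 2L, b + 1L]         # step 2
        cur[a + 1L, b + 1L] <- tot
      }
    }
    counts[[k + 1L]] <- cur
  }
  dim <- counts[[1L]][1L, 1L]
  if (dim < 1)
    stop("sector contains no CSFs (empty Shavitt graph)", call. = FALSE)
  structure(
    list(space = space, dim = as.numeric(dim), counts = counts,
         a_max = a_max, b_max = b_max, cache = new.env(parent = emptyenv())),
    class = "drt")
}

is_drt <- function(x) inherits(x, "drt")

assert_drt <- function(x) {
  if (!is_drt(x)) stop("expected a `drt` object", call. = FALSE)
  invisible(x)
}

#' @export
print.drt <- function(x, ...) {
  cat(sprintf("<drt> sector (n = %d, N = %d, S = %s): %g CSFs\n",
              x$space$n_orbitals, x$space$n_electrons,
              format_half_integer(x$space$twice_S), x$dim))
  invisible(x)
}

# Child node of (a, b) under a step code, or NULL when outside the graph.
drt_child <- function(drt, a, b, code) {
  if (code == 0L) c(a, b)
  else if (code == 1L) c(a, b + 1L)
  else if (code == 2L) c(a + 1L, b - 1L)
  else c(a + 1L, b)
}

drt_count <- function(drt, level, a, b) {
  if (a < 0L || b < 0L || a > drt$a_max || b > drt$b_max) return(0)
  drt$counts[[level + 1L]][a + 1L, b + 1L]
}

#' Dimension of a CSF basis
#'
#' Closed-form Weyl-Paldus count of the spin-adapted basis,
#' `(2S + 1) / (n + 1) * C(n + 1, N/2 - S) * C(n + 1, N/2 + S + 1)`.
#' Equals the number of paths of [build_drt()].
#'
#' @param space A [spin_space()].
#' @return Number of CSFs (numeric).
#' @examples
#' csf_dimension(spin_space(6, 6, 0))    # 175
#' csf_dimension(spin_space(10, 10, 0))  # 19404
#' @export
csf_dimension <- function(space) {
  assert_spin_space(space)
  n <- space$n_orbitals
  N <- space$n_electrons
  b <- space$twice_S
  (b + 1) / (n + 1) * choose(n + 1, (N - b) / 2) * choose(n + 1, (N + b) / 2 + 1)
}

#' Map a lexicographic index to its CSF, and back
#'
#' CSFs are ordered lexicographically in their step vectors with
#' `0 < u < d < 2`, orbital 1 most significant; indices are 1-based. The
#' two maps are mutually inverse bijections over `1:drt$dim`.
#'
#' @param drt A [build_drt()] result.
#' @param index CSF index in `1:drt$dim`.
#' @return [index_to_csf()] returns a [csf()]; [csf_to_index()] returns an
#'   integer index.
#' @examples
#' d <- build_drt(spin_space(2, 2, 0))
#' format(index_to_csf(d, 1))  # |0,2>
#' csf_to_index(d, csf("ud", d$space))
#' @export
index_to_csf <- function(drt, index) {
  assert_drt(drt)
  index <- as.numeric(index)
  if (length(index) != 1L || is.na(index) || index < 1 || index > drt$dim ||
      index != floor(index))
    stop(sprintf("index must be an integer in 1..%g", drt$dim), call. = FALSE)
  n <- drt$space$n_orbitals
  codes <- integer(n)
  a <- 0L; b <- 0L
  rem <- index
  for (k in 1:n) {
    placed <- FALSE
    for (code in 0:3) {
      ch <- drt_child(drt, a, b, code)
      w <- drt_count(drt, k, ch[1L], ch[2L])
      if (rem <= w && w > 0) {
        codes[k] <- code
        a <- ch[1L]; b <- ch[2L]
        placed <- TRUE
        break
      }
      rem <- rem - w
    }
    if (!placed) stop("internal error: DRT walk exhausted", call. = FALSE)
  }
  csf(codes, drt$space)
}

#' @rdname index_to_csf
#' @param x A [csf()] belonging to the same sector.
#' @export
csf_to_index <- function(drt, x) {
  assert_drt(drt)
  assert_csf(x)
  if (!identical(unclass(x$space), unclass(drt$space)))
    stop("CSF does not belong to this DRT's sector", call. = FALSE)
  n <- drt$space$n_orbitals
  a <- 0L; b <- 0L
  idx <- 1
  for (k in 1:n) {
    code_k <- x$steps[k]
    if (code_k > 0L) {
      for (code in 0:(code_k - 1L)) {
        ch <- drt_child(drt, a, b, code)
        idx <- idx + drt_count(drt, k, ch[1L], ch[2L])
      }
    }
    ch <- drt_child(drt, a, b, code_k)
    if (drt_count(drt, k, ch[1L], ch[2L]) == 0)
      stop("CSF is not a path of this DRT", call. = FALSE)
    a <- ch[1L]; b <- ch[2L]
  }
  as.integer(idx)
}

#' Enumerate all CSFs of a sector
#'
#' @param drt A [build_drt()] result.
#' @return A tibble with one row per CSF: `index`, `steps` (compact step
#'   string, e.g. `"u0ud"`), `n_open` (number of singly occupied
#'   orbitals), and `occ` (list column of occupation vectors).
#' @examples
#' enumerate_csfs(build_drt(spin_space(2, 2, 0)))
#' @export
enumerate_csfs <- function(drt) {
  assert_drt(drt)
  n <- drt$space$n_orbitals
  m <- as.integer(drt$dim)
  steps <- character(m)
  n_open <- integer(m)
  occs <- vector("list", m)
  for (i in seq_len(m)) {
    x <- index_to_csf(drt, i)
    steps[i] <- csf_string(x)
    n_open[i] <- sum(x$occ == 1L)
    occs[[i]] <- x$occ
  }
  tibble::tibble(index = seq_len(m), steps = steps, n_open = n_open, occ = occs)
}

# All step-code matrices of a sector as an m x n integer matrix (row = CSF).
# Cached on the DRT; the workhorse for occupation lookups in the generator
# and engine code.
drt_step_matrix <- function(drt) {
  cache <- drt$cache
  if (!is.null(cache$step_matrix)) return(cache$step_matrix)
  n <- drt$space$n_orbitals
  m <- as.integer(drt$dim)
  sm <- matrix(0L, m, n)
  for (i in seq_len(m)) sm[i, ] <- index_to_csf(drt, i)$steps
  cache$step_matrix <- sm
  sm
}

drt_occ_matrix <- function(drt) {
  cache <- drt$cache
  if (!is.null(cache$occ_matrix)) return(cache$occ_matrix)
  sm <- drt_step_matrix(drt)
  om <- matrix(STEP_OCC[sm + 1L], nrow(sm), ncol(sm))
  cache$occ_matrix <- om
  om
}

# Map occupation-pattern string -> CSF indices sharing that pattern.
drt_occ_index <- function(drt) {
  cache <- drt$cache
  if (!is.null(cache$occ_index)) return(cache$occ_index)
  om <- drt_occ_matrix(drt)
  keys <- apply(om, 1L, paste, collapse = "")
  cache$occ_index <- split(seq_along(keys), keys)
  cache$occ_index
}

drt_csf <- function(drt, i) {
  sm <- drt_step_matrix(drt)
  codes <- sm[i, ]
  b <- cumsum(STEP_DB[codes + 1L])
  structure(list(steps = codes, occ = STEP_OCC[codes + 1L], b = b,
                 space = drt$space), class = "csf")
}

#' Paldus row table of a DRT
#'
#' Nodes of the Shavitt graph that lie on at least one tail-to-head path,
#' with their Paldus rows and subtree path counts.
#'
#' @param drt A [build_drt()] result.
#' @return A tibble of graph nodes: `level`, `a`, `b`, `c`, `count` (paths
#'   from the node up to the sector head) and `lower_count` (paths from
#'   the graph tail up to the node); `count * lower_count` is the number
#'   of CSFs through the node.
#' @export
drt_nodes <- function(drt) {
  assert_drt(drt)
  n <- drt$space$n_orbitals
  # forward (tail-to-node) path counts, to prune unreachable rows
  lower <- vector("list", n + 1L)
  for (k in 0:n) lower[[k + 1L]] <- matrix(0, drt$a_max + 1L, drt$b_max + 1L)
  lower[[1L]][1L, 1L] <- 1
  for (k in seq_len(n)) {
    prev <- lower[[k]]
    cur <- lower[[k + 1L]]
    nz <- which(prev > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      a <- nz[r, 1L] - 1L; b <- nz[r, 2L] - 1L
      for (code in 0:3) {
        ch <- drt_child(drt, a, b, code)
        if (ch[1L] < 0L || ch[2L] < 0L || ch[1L] > drt$a_max ||
            ch[2L] > drt$b_max) next
        cur[ch[1L] + 1L, ch[2L] + 1L] <-
          cur[ch[1L] + 1L, ch[2L] + 1L] + prev[a + 1L, b + 1L]
      }
    }
    lower[[k + 1L]] <- cur
  }
  out <- list()
  for (k in 0:n) {
    cnt <- drt$counts[[k + 1L]]
    low <- lower[[k + 1L]]
    nz <- which(cnt > 0 & low > 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) next
    a <- nz[, 1L] - 1L
    b <- nz[, 2L] - 1L
    out[[length(out) + 1L]] <- tibble::tibble(
      level = k, a = a, b = b, c = k - a - b,
      count = cnt[nz], lower_count = low[nz])
  }
  dplyr::bind_rows(out)
}
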