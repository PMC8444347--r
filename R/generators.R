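#' Sparse matrix of a one-body spin-free generator
#'
#' Builds the full matrix of `E_ij = sum_sigma a^+_{i sigma} a_{j sigma}`
#' over the CSF basis of a sector. The diagonal case `i == j` is the
#' occupation-number operator. Matrices are cached on the DRT, and
#' `E_ji = t(E_ij)` is exploited.
#'
#' @param drt A [build_drt()] result.
#' @param i,j Spatial orbital indices.
#' @return A `dgCMatrix` of dimension `drt$dim` x `drt$dim`; entry
#'   `[bra, ket]` is `<bra| E_ij |ket>`.
#' @examples
#' d <- build_drt(spin_space(2, 2, 0))
#' generator_matrix(d, 1, 2)
#' @export
generator_matrix <- function(drt, i, j) {
  assert_drt(drt)
  n <- drt$space$n_orbitals
  i <- as.integer(i); j <- as.integer(j)
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    stop("orbital indices out of range", call. = FALSE)
  key <- paste0("E", i, ",", j)
  cache <- drt$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  tkey <- paste0("E", j, ",", i)
  if (!is.null(cache[[tkey]])) {
    out <- Matrix::t(cache[[tkey]])
    cache[[key]] <- out
    return(out)
  }
  m <- as.integer(drt$dim)
  if (i == j) {
    occ <- drt_occ_matrix(drt)[, i]
    out <- Matrix::Diagonal(m, x = as.numeric(occ))
    out <- methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
    cache[[key]] <- out
    return(out)
  }
  sm <- drt_step_matrix(drt)
  om <- drt_occ_matrix(drt)
  occ_idx <- drt_occ_index(drt)
  lo <- min(i, j); hi <- max(i, j)
  out_cols <- setdiff(seq_len(n), lo:hi)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (ket in seq_len(m)) {
    occ_ket <- om[ket, ]
    if (occ_ket[j] == 0L || occ_ket[i] == 2L) next
    target <- occ_ket
    target[i] <- target[i] + 1L
    target[j] <- target[j] - 1L
    cands <- occ_idx[[paste(target, collapse = "")]]
    if (is.null(cands)) next
    ket_csf <- drt_csf(drt, ket)
    for (bra in cands) {
      if (length(out_cols) > 0L &&
          any(sm[bra, out_cols] != sm[ket, out_cols])) next
      bra_csf <- drt_csf(drt, bra)
      val <- window_element(bra_csf$steps, bra_csf$b, ket_csf$steps,
                            ket_csf$b, c(i, j), "E")
      if (val != 0) {
        ii <- c(ii, bra); jj <- c(jj, ket); xx <- c(xx, val)
      }
    }
  }
  out <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, m))
  cache[[key]] <- out
  out
}

#' Sparse matrix of a two-body spin-free operator
#'
#' Returns `e_ij,kl = E_ij E_kl - delta_jk E_il` over the CSF basis,
#' assembled exactly from the one-body generator matrices per the defining
#' identity.
#'
#' @inheritParams generator_matrix
#' @param k,l Spatial orbital indices.
#' @return A sparse `dgCMatrix`.
#' @export
two_body_matrix <- function(drt, i, j, k, l) {
  assert_drt(drt)
  n <- drt$space$n_orbitals
  idx <- as.integer(c(i, j, k, l))
  if (any(idx < 1L) || any(idx > n))
    stop("orbital indices out of range", call. = FALSE)
  out <- generator_matrix(drt, idx[1], idx[2]) %*% generator_matrix(drt, idx[3], idx[4])
  if (idx[2] == idx[3]) out <- out - generator_matrix(drt, idx[1], idx[4])
  methods::as(out, "CsparseMatrix")
}

route_tibble <- function(kind = character(), i = integer(), j = integer(),
                         k = integer(), l = integer(), coefficient = numeric()) {
  tibble::tibble(kind = kind, i = i, j = j, k = k, l = l,
                 coefficient = coefficient)
}

#' Identify the excitation connecting two CSFs
#'
#' Classifies the pair (diagonal, single, double, or exchange-type, i.e.
#' identical occupations but different open-shell coupling) and enumerates
#' every index route `(i, j[, k, l])` with a nonzero coupling coefficient —
#' each distinct 4-index slot of the two-body operator table exactly once.
#' Exchange-type pairs can be reached through multiple non-unique orbital
#' combinations `e_ij,ji`; all contributing routes are reported with their
#' individual coefficients, as needed for unbiased RDM accumulation.
#'
#' @param bra,ket [csf()] objects from the same sector.
#' @return An object of class `"excitation_record"`: a list with `type`
#'   (`"diagonal"`, `"single"`, `"double"`, `"exchange"`, or
#'   `"not_connected"`) and `routes`, a tibble with columns `kind`
#'   (`"one_body"` or `"two_body"`), `i`, `j`, `k`, `l` (`NA` for one-body)
#'   and `coefficient`.
#' @export
identify_excitation <- function(bra, ket) {
  assert_csf(bra); assert_csf(ket)
  if (!same_sector(bra, ket))
    stop("bra and ket belong to different sectors", call. = FALSE)
  if (identical(bra$steps, ket$steps))
    return(structure(list(type = "diagonal", routes = diagonal_routes(ket)),
                     class = "excitation_record"))
  docc <- bra$occ - ket$occ
  n_moved <- sum(pmax(docc, 0L))
  type <- if (n_moved == 0L) "exchange"
          else if (n_moved == 1L) "single"
          else if (n_moved == 2L) "double"
          else "not_connected"
  routes <- if (type == "not_connected") route_tibble()
            else offdiagonal_routes(bra, ket, docc, n_moved)
  structure(list(type = type, routes = routes), class = "excitation_record")
}

# All nonzero routes between two *different* CSFs of the same sector; every
# distinct 4-index slot appears exactly once (e_ij,kl = e_kl,ij images are
# listed individually with their common coefficient).
offdiagonal_routes <- function(bra, ket, docc = bra$occ - ket$occ,
                               n_moved = sum(pmax(docc, 0L))) {
  n <- ket$space$n_orbitals
  rt <- list()
  add <- function(kind, i, j, k, l, val) {
    if (abs(val) > 1e-14)
      rt[[length(rt) + 1L]] <<- list(kind, i, j, k, l, val)
  }
  if (n_moved == 0L) {
    occ_orbs <- which(ket$occ > 0L)
    for (a in occ_orbs) for (b in occ_orbs) {
      if (a == b) next
      add("two_body", a, b, b, a, csf_two_body_element(bra, ket, a, b, b, a))
    }
  } else if (n_moved == 1L) {
    i <- which(docc == 1L); j <- which(docc == -1L)
    w <- window_element(bra$steps, bra$b, ket$steps, ket$b, c(i, j), "E")
    add("one_body", i, j, NA_integer_, NA_integer_, w)
    for (k in seq_len(n)) {
      if (k == i || k == j || ket$occ[k] > 0L) {
        v <- csf_two_body_element(bra, ket, i, j, k, k)
        add("two_body", i, j, k, k, v)
        add("two_body", k, k, i, j, v)   # e_kk,ij = e_ij,kk
      }
      if (k != i && k != j && ket$occ[k] > 0L) {
        v <- csf_two_body_element(bra, ket, i, k, k, j)
        add("two_body", i, k, k, j, v)
        add("two_body", k, j, i, k, v)   # e_kj,ik = e_ik,kj
      }
    }
  } else if (n_moved == 2L) {
    pos <- rep(which(docc > 0L), times = docc[docc > 0L])
    neg <- rep(which(docc < 0L), times = -docc[docc < 0L])
    tuples <- list(
      c(pos[1], neg[1], pos[2], neg[2]), c(pos[2], neg[2], pos[1], neg[1]),
      c(pos[1], neg[2], pos[2], neg[1]), c(pos[2], neg[1], pos[1], neg[2]))
    seen <- character(0)
    for (p in tuples) {
      key <- paste(p, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      add("two_body", p[1], p[2], p[3], p[4],
          csf_two_body_element(bra, ket, p[1], p[2], p[3], p[4]))
    }
  }
  routes_from_list(rt)
}

# Diagonal routes of one CSF: gamma_ii = n_i,
# Gamma_ii,kk = n_i n_k - delta_ik n_i, and the exchange-diagonal
# Gamma_ij,ji = <mu| e_ij,ji |mu> for occupied i != j.
diagonal_routes <- function(ket) {
  n <- ket$space$n_orbitals
  occ <- ket$occ
  rt <- list()
  add <- function(kind, i, j, k, l, val) {
    if (abs(val) > 1e-14)
      rt[[length(rt) + 1L]] <<- list(kind, i, j, k, l, val)
  }
  for (i in seq_len(n)) {
    add("one_body", i, i, NA_integer_, NA_integer_, occ[i])
    for (k in seq_len(n))
      add("two_body", i, i, k, k, occ[i] * occ[k] - (i == k) * occ[i])
  }
  occ_orbs <- which(occ > 0L)
  for (i in occ_orbs) for (j in occ_orbs) {
    if (i == j) next
    add("two_body", i, j, j, i,
        window_element(ket$steps, ket$b, ket$steps, ket$b, c(i, j, j, i), "e"))
  }
  routes_from_list(rt)
}

routes_from_list <- function(rt) {
  if (length(rt) == 0L) return(route_tibble())
  tibble::tibble(
    kind = vapply(rt, `[[`, "", 1L),
    i = vapply(rt, function(x) as.integer(x[[2L]]), 1L),
    j = vapply(rt, function(x) as.integer(x[[3L]]), 1L),
    k = vapply(rt, function(x) as.integer(x[[4L]]), 1L),
    l = vapply(rt, function(x) as.integer(x[[5L]]), 1L),
    coefficient = vapply(rt, function(x) as.numeric(x[[6L]]), 1))
}

#' @export
print.excitation_record <- function(x, ...) {
  cat(sprintf("<excitation_record> type = %s, %d route(s)\n",
              x$type, nrow(x$routes)))
  if (nrow(x$routes) > 0L) print(x$routes, n = 10)
  invisible(x)
}

#' Total-spin operator over a CSF basis
#'
#' Assembles `S^2 = sum_p S_p^2 + sum_{p != q} S_p . S_q` through the
#' operator identities `S_p . S_q = -1/2 e_pq,qp - 1/4 e_pp,qq` and
#' `S_p^2 = 3/4 (n_p - e_pp,pp)`. On a spin-adapted basis this must equal
#' `S(S+1)` times the identity, which is the defining property the test
#' suite asserts.
#'
#' @param drt A [build_drt()] result.
#' @return Sparse `S^2` matrix.
#' @export
s2_matrix <- function(drt) {
  assert_drt(drt)
  n <- drt$space$n_orbitals
  m <- as.integer(drt$dim)
  out <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(m, m))
  for (p in seq_len(n)) {
    npd <- generator_matrix(drt, p, p)
    out <- out + 0.75 * (npd - (two_body_matrix(drt, p, p, p, p)))
    for (q in seq_len(n)) {
      if (p == q) next
      out <- out - 0.5 * two_body_matrix(drt, p, q, q, p) -
        0.25 * two_body_matrix(drt, p, p, q, q)
    }
  }
  methods::as(out, "CsparseMatrix")
}
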