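# Determinant-level backend for coupling coefficients.
#
# A CSF is a genealogical spin coupling: orbital by orbital, each singly
# occupied orbital adds a spin 1/2 to the cumulative spin S_k (step u couples
# up, step d couples down).  Expanding the CSF in Slater determinants at a
# fixed projection M therefore gives a product of elementary Clebsch-Gordan
# factors, one per open shell.  Spin-free generators are SU(2) scalars, so a
# matrix element between two CSFs depends only on the step values inside the
# orbital window spanned by the operator indices and on the cumulative spin
# entering the window: segments outside the window contribute only a
# delta on equal step values.  The evaluation below exploits exactly that
# locality: the head of the path is replaced by a ferromagnetic stack of
# b = 2 S_(lo-1) spectator u-steps (same entering spin, phases from fully
# paired electrons cancel), the tail is dropped, and the small windowed
# system is contracted in its determinant expansion.

# Determinant encoding: integer per orbital, 0 empty, 1 alpha, 2 beta, 3 both.
DET_NOCC <- c(0L, 1L, 1L, 2L)

# CG factors for coupling one spin-1/2 onto spin b/2, in twice-integer
# arithmetic. `b_prev` is 2S before the step, `sigma` = +/-1 the added spin
# projection (2m_s), `m2_new` the accumulated 2M after the step, `up` logical
# for a u step (S -> S + 1/2) vs a d step (S -> S - 1/2).
cg_half <- function(b_prev, m2_new, sigma, up) {
  if (up) {
    if (sigma > 0) sqrt((b_prev + m2_new + 1) / (2 * (b_prev + 1)))
    else           sqrt((b_prev - m2_new + 1) / (2 * (b_prev + 1)))
  } else {
    if (sigma > 0) -sqrt((b_prev - m2_new + 1) / (2 * (b_prev + 1)))
    else            sqrt((b_prev + m2_new + 1) / (2 * (b_prev + 1)))
  }
}

# Expand a step-code vector into determinants at projection 2M = m2_target.
# Returns list(dets = integer matrix, coef = numeric vector); determinant
# creation-operator order is orbital-major with alpha before beta, matching
# the genealogical product, so coefficients are pure CG products.
csf_determinants <- function(codes, m2_target = NULL) {
  n <- length(codes)
  b_seq <- cumsum(STEP_DB[codes + 1L])
  if (is.null(m2_target)) m2_target <- b_seq[n]
  open_pos <- which(codes == 1L | codes == 2L)
  n_open <- length(open_pos)
  base <- integer(n)
  base[codes == 3L] <- 3L
  if (n_open == 0L) {
    if (m2_target != 0L) return(list(dets = matrix(integer(0), 0, n), coef = numeric(0)))
    return(list(dets = matrix(base, 1L, n), coef = 1))
  }
  # remaining open shells after each open position (for pruning)
  rem_after <- (n_open - 1L):0L
  dets <- list(); coefs <- numeric(0)
  sigma <- integer(n_open)
  recurse <- function(pos_i, m2, amp) {
    if (pos_i > n_open) {
      if (m2 == m2_target) {
        det <- base
        det[open_pos] <- ifelse(sigma > 0L, 1L, 2L)
        dets[[length(dets) + 1L]] <<- det
        coefs[length(coefs) + 1L] <<- amp
      }
      return(invisible(NULL))
    }
    k <- open_pos[pos_i]
    b_prev <- if (k == 1L) 0L else b_seq[k - 1L]
    up <- codes[k] == 1L
    for (s in c(1L, -1L)) {
      m2_new <- m2 + s
      if (abs(m2_target - m2_new) > rem_after[pos_i]) next
      f <- cg_half(b_prev, m2_new, s, up)
      if (f == 0) next
      sigma[pos_i] <<- s
      recurse(pos_i + 1L, m2_new, amp * f)
    }
    invisible(NULL)
  }
  recurse(1L, 0L, 1)
  if (length(dets) == 0L) return(list(dets = matrix(integer(0), 0, n), coef = numeric(0)))
  list(dets = do.call(rbind, dets), coef = coefs)
}

# Fermionic position of (orbital k, spin sigma) in the orbital-major,
# alpha-before-beta creation-operator ordering.
det_position <- function(det, k, sigma) {
  before <- if (k > 1L) sum(DET_NOCC[det[seq_len(k - 1L)] + 1L]) else 0L
  extra <- if (sigma == 2L && (det[k] == 1L || det[k] == 3L)) 1L else 0L
  before + extra + 1L
}

# Apply a_{k,sigma} (sigma: 1 alpha, 2 beta); NULL when unoccupied.
det_annihilate <- function(det, k, sigma) {
  has <- if (sigma == 1L) det[k] %in% c(1L, 3L) else det[k] %in% c(2L, 3L)
  if (!has) return(NULL)
  sgn <- if (det_position(det, k, sigma) %% 2L == 1L) 1 else -1
  det[k] <- det[k] - sigma
  list(det = det, sign = sgn)
}

# Apply a^dagger_{k,sigma}; NULL when already occupied.
det_create <- function(det, k, sigma) {
  free <- if (sigma == 1L) det[k] %in% c(0L, 2L) else det[k] %in% c(0L, 1L)
  if (!free) return(NULL)
  det[k] <- det[k] + sigma
  sgn <- if (det_position(det, k, sigma) %% 2L == 1L) 1 else -1
  list(det = det, sign = sgn)
}

# E_ij |det> = sum_sigma a^dag_{i sigma} a_{j sigma} |det>, as a list of
# (det, amplitude) accumulated into an environment keyed by det string.
det_apply_E <- function(det, amp, i, j, acc) {
  if (i == j) {
    nocc <- DET_NOCC[det[i] + 1L]
    if (nocc > 0L) acc_add(acc, det, amp * nocc)
    return(invisible(NULL))
  }
  for (sigma in c(1L, 2L)) {
    an <- det_annihilate(det, j, sigma)
    if (is.null(an)) next
    cr <- det_create(an$det, i, sigma)
    if (is.null(cr)) next
    acc_add(acc, cr$det, amp * an$sign * cr$sign)
  }
  invisible(NULL)
}

acc_new <- function() new.env(parent = emptyenv())

acc_add <- function(acc, det, amp) {
  key <- paste(det, collapse = "")
  cur <- acc[[key]]
  if (is.null(cur)) acc[[key]] <- list(det = det, amp = amp)
  else acc[[key]]$amp <- cur$amp + amp
  invisible(NULL)
}

# <bra_codes| op |ket_codes> for mini systems, evaluated in the determinant
# expansion at the common maximal projection. `apply_op` maps (det, amp, acc).
mini_element <- function(bra_codes, ket_codes, apply_op) {
  b_bra <- sum(STEP_DB[bra_codes + 1L])
  b_ket <- sum(STEP_DB[ket_codes + 1L])
  if (b_bra != b_ket) return(0)
  m2 <- b_ket
  ket_exp <- csf_determinants(ket_codes, m2)
  if (nrow(ket_exp$dets) == 0L) return(0)
  bra_exp <- csf_determinants(bra_codes, m2)
  if (nrow(bra_exp$dets) == 0L) return(0)
  acc <- acc_new()
  for (r in seq_len(nrow(ket_exp$dets)))
    apply_op(ket_exp$dets[r, ], ket_exp$coef[r], acc)
  bra_keys <- apply(bra_exp$dets, 1L, paste, collapse = "")
  val <- 0
  for (r in seq_along(bra_keys)) {
    hit <- acc[[bra_keys[r]]]
    if (!is.null(hit)) val <- val + bra_exp$coef[r] * hit$amp
  }
  val
}

# Windowed evaluation of <bra| E_ij |ket> or <bra| e_ij,kl |ket> between two
# CSFs of the same sector, given as step-code vectors with cumulative b.
window_element <- function(bra_codes, bra_b, ket_codes, ket_b, idx, kind) {
  n <- length(ket_codes)
  lo <- min(idx); hi <- max(idx)
  out_mask <- rep(TRUE, n)
  out_mask[lo:hi] <- FALSE
  if (any(bra_codes[out_mask] != ket_codes[out_mask])) return(0)
  b_hi_ket <- ket_b[hi]
  if (bra_b[hi] != b_hi_ket) return(0)
  b0 <- if (lo > 1L) ket_b[lo - 1L] else 0L
  spect <- rep(1L, b0)
  mini_ket <- c(spect, ket_codes[lo:hi])
  mini_bra <- c(spect, bra_codes[lo:hi])
  sh <- function(p) b0 + (p - lo + 1L)
  if (kind == "E") {
    i <- sh(idx[1L]); j <- sh(idx[2L])
    mini_element(mini_bra, mini_ket, function(det, amp, acc)
      det_apply_E(det, amp, i, j, acc))
  } else {
    i <- sh(idx[1L]); j <- sh(idx[2L]); k <- sh(idx[3L]); l <- sh(idx[4L])
    # e_ij,kl = E_ij E_kl - delta_jk E_il
    apply_e <- function(det, amp, acc) {
      mid <- acc_new()
      det_apply_E(det, amp, k, l, mid)
      for (key in ls(mid)) {
        ent <- mid[[key]]
        det_apply_E(ent$det, ent$amp, i, j, acc)
      }
      if (idx[2L] == idx[3L]) det_apply_E(det, -amp, i, l, acc)
    }
    mini_element(mini_bra, mini_ket, apply_e)
  }
}

#' Coupling coefficient of a one-body generator between two CSFs
#'
#' Evaluates the unitary-group generator matrix element
#' `<bra| E_ij |ket>` with `E_ij = sum_sigma a^+_{i sigma} a_{j sigma}`.
#' The value depends only on the step values inside the orbital window
#' `[min(i,j), max(i,j)]` and the cumulative spin entering it; the
#' evaluation contracts exactly that window (with a ferromagnetic spectator
#' stack carrying the entering spin), which is the fast path validated
#' against the full sparse matrix of [generator_matrix()].
#'
#' @param bra,ket [csf()] objects from the same sector.
#' @param i,j Spatial orbital indices (1-based).
#' @return The matrix element (numeric scalar).
#' @examples
#' s <- spin_space(2, 2, 0)
#' coupling_coefficient(csf("ud", s), csf("20", s), 2, 1)  # sqrt(2)
#' @export
coupling_coefficient <- function(bra, ket, i, j) {
  assert_csf(bra); assert_csf(ket)
  if (!same_sector(bra, ket))
    stop("bra and ket belong to different sectors", call. = FALSE)
  n <- ket$space$n_orbitals
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || i > n || j < 1L || j > n)
    stop("orbital indices out of range", call. = FALSE)
  if (i == j) {
    if (identical(bra$steps, ket$steps)) return(as.numeric(ket$occ[i]))
    return(0)
  }
  docc <- bra$occ - ket$occ
  expected <- integer(n); expected[i] <- 1L; expected[j] <- -1L
  if (!all(docc == expected)) return(0)
  window_element(bra$steps, bra$b, ket$steps, ket$b, c(i, j), "E")
}

# Two-body element <bra| e_ij,kl |ket> via the windowed contraction.
csf_two_body_element <- function(bra, ket, i, j, k, l) {
  n <- ket$space$n_orbitals
  docc <- bra$occ - ket$occ
  expected <- integer(n)
  expected[i] <- expected[i] + 1L
  expected[j] <- expected[j] - 1L
  expected[k] <- expected[k] + 1L
  expected[l] <- expected[l] - 1L
  if (!all(docc == expected)) return(0)
  window_element(bra$steps, bra$b, ket$steps, ket$b, c(i, j, k, l), "e")
}
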