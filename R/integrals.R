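#' Construct an electronic integral set
#'
#' Holds the one-electron integrals `t_ij` (symmetric), the two-electron
#' integrals `V_ijkl` in chemists' `(ij|kl)` notation with 8-fold
#' permutational symmetry, and a scalar core energy. The Hamiltonian
#' convention throughout the package is
#' `H = sum_ij t_ij E_ij + 1/2 sum_ijkl V_ijkl e_ij,kl + E_core`.
#'
#' @param t_one Symmetric `n x n` matrix of one-electron integrals (hartree).
#' @param v_two Either a full `n^4` array `V[i,j,k,l]`, or `NULL` for all
#'   zeros. The array is symmetrized over the 8-fold `(ij|kl)` index group.
#' @param core_energy Scalar constant shift.
#' @param n_electrons,ms2 Optional sector metadata carried into FCIDUMP
#'   headers.
#' @return An object of class `"integral_set"`.
#' @export
integral_set <- function(t_one, v_two = NULL, core_energy = 0,
                         n_electrons = NA_integer_, ms2 = 0L) {
  t_one <- as.matrix(t_one)
  n <- nrow(t_one)
  if (ncol(t_one) != n) stop("`t_one` must be square", call. = FALSE)
  if (max(abs(t_one - t(t_one))) > 1e-10)
    stop("`t_one` must be symmetric", call. = FALSE)
  t_one <- (t_one + t(t_one)) / 2
  if (is.null(v_two)) v_two <- array(0, c(n, n, n, n))
  if (!identical(dim(v_two), rep(n, 4L)))
    stop("`v_two` must be an n^4 array matching `t_one`", call. = FALSE)
  v_two <- symmetrize_v(v_two)
  structure(
    list(n_orbitals = n, t_one = t_one, v_two = v_two,
         core_energy = as.numeric(core_energy),
         n_electrons = as.integer(n_electrons), ms2 = as.integer(ms2),
         cache = new.env(parent = emptyenv())),
    class = "integral_set")
}

# Average V over the 8-fold (ij|kl) permutation group.
symmetrize_v <- function(v) {
  out <- v
  out <- (out + aperm(v, c(2, 1, 3, 4)) + aperm(v, c(1, 2, 4, 3)) +
            aperm(v, c(2, 1, 4, 3)) + aperm(v, c(3, 4, 1, 2)) +
            aperm(v, c(4, 3, 1, 2)) + aperm(v, c(3, 4, 2, 1)) +
            aperm(v, c(4, 3, 2, 1))) / 8
  out
}

is_integral_set <- function(x) inherits(x, "integral_set")

assert_integral_set <- function(x) {
  if (!is_integral_set(x)) stop("expected an `integral_set`", call. = FALSE)
  invisible(x)
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf(
    "<integral_set> %d orbitals, %d nonzero t, %d nonzero V, core = %g\n",
    x$n_orbitals, sum(x$t_one != 0), sum(x$v_two != 0), x$core_energy))
  invisible(x)
}

#' Hubbard model integrals
#'
#' Nearest-neighbour hopping `-t` on a chain or ring of sites with on-site
#' repulsion `U` (`V_iiii = U`). A two-site ring is treated as the chain
#' (a single bond, not a doubled one).
#'
#' @param n_sites Number of sites (>= 2).
#' @param t Hopping amplitude (enters as `-t` on bonds).
#' @param U On-site repulsion.
#' @param topology `"chain"` or `"ring"`.
#' @return An [integral_set()].
#' @examples
#' hubbard_model(2, t = 1, U = 4)
#' @export
hubbard_model <- function(n_sites, t = 1, U = 4,
                          topology = c("chain", "ring")) {
  topology <- match.arg(topology)
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("`n_sites` must be at least 2", call. = FALSE)
  t_one <- matrix(0, n_sites, n_sites)
  for (i in seq_len(n_sites - 1L)) {
    t_one[i, i + 1L] <- -t
    t_one[i + 1L, i] <- -t
  }
  if (topology == "ring" && n_sites > 2L) {
    t_one[n_sites, 1L] <- t_one[n_sites, 1L] - t
    t_one[1L, n_sites] <- t_one[1L, n_sites] - t
  }
  v <- array(0, rep(n_sites, 4L))
  for (i in seq_len(n_sites)) v[i, i, i, i] <- U
  integral_set(t_one, v, n_electrons = n_sites)
}

#' Antiferromagnetic exchange-cluster model integrals
#'
#' A caricature of localized, site-ordered magnetic centers: each center
#' carries `orbitals_per_center` orbitals with on-site repulsion `U` and a
#' ferromagnetic intra-center exchange `K` (`(pq|qp) = K` for `p != q` on
#' one center) that enforces local Hund coupling; adjacent centers are
#' linked by weak hopping `-t` between like orbitals, which generates an
#' antiferromagnetic inter-center superexchange of order `4 t^2 / U`. At
#' half filling with strong `K` and `U`, the ground state is a low-spin
#' combination of local high-spin centers and the energies per total-spin
#' sector form an antiferromagnetic spin ladder.
#'
#' @param n_centers Number of magnetic centers (chain topology).
#' @param orbitals_per_center Orbitals on each center.
#' @param intra_exchange Ferromagnetic intra-center exchange `K > 0`.
#' @param inter_hopping Hopping `t` between like orbitals of neighbours.
#' @param on_site_U On-site repulsion `U`.
#' @return An [integral_set()] with `n_centers * orbitals_per_center`
#'   orbitals; orbital `(c - 1) * orbitals_per_center + m` is orbital `m`
#'   of center `c`.
#' @examples
#' exchange_cluster_model(2, 2, intra_exchange = 1, inter_hopping = 0.1,
#'                        on_site_U = 8)
#' @export
exchange_cluster_model <- function(n_centers, orbitals_per_center,
                                   intra_exchange = 1, inter_hopping = 0.1,
                                   on_site_U = 8) {
  n_centers <- as.integer(n_centers)
  opc <- as.integer(orbitals_per_center)
  if (n_centers < 1L || opc < 1L)
    stop("center and orbital counts must be positive", call. = FALSE)
  if (intra_exchange < 0)
    stop("`intra_exchange` must be positive to enforce Hund coupling",
         call. = FALSE)
  n <- n_centers * opc
  orb <- function(c, m) (c - 1L) * opc + m
  t_one <- matrix(0, n, n)
  if (n_centers > 1L) {
    for (c in seq_len(n_centers - 1L)) for (m in seq_len(opc)) {
      i <- orb(c, m); j <- orb(c + 1L, m)
      t_one[i, j] <- -inter_hopping
      t_one[j, i] <- -inter_hopping
    }
  }
  v <- array(0, rep(n, 4L))
  for (i in seq_len(n)) v[i, i, i, i] <- on_site_U
  for (c in seq_len(n_centers)) for (p in seq_len(opc)) for (q in seq_len(opc)) {
    if (p == q) next
    i <- orb(c, p); j <- orb(c, q)
    v[i, j, j, i] <- intra_exchange
  }
  integral_set(t_one, v, n_electrons = n)
}

#' Read and write FCIDUMP integral files
#'
#' The standard FCIDUMP dialect: a `&FCI` namelist header with `NORB`,
#' `NELEC`, `MS2`, `ORBSYM`, `ISYM`, terminated by `&END` (or `/`),
#' followed by records `value i j k l`. Two-electron records carry four
#' nonzero indices in chemists' `(ij|kl)` notation, one-electron records
#' have `k = l = 0`, and the core energy has all indices zero. On reading,
#' permutation-equivalent records fold into one canonical entry; duplicate
#' records that disagree beyond `1e-10` are an error.
#'
#' @param path File path.
#' @return [read_fcidump()] returns an [integral_set()];
#'   [write_fcidump()] returns `path` invisibly.
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr_end <- grep("(&END|/)\\s*$", toupper(lines))[1]
  if (is.na(hdr_end) || !grepl("^&FCI", toupper(lines[1])))
    stop("malformed FCIDUMP header: missing &FCI ... &END", call. = FALSE)
  header <- paste(lines[1:hdr_end], collapse = " ")
  get_int <- function(key) {
    m <- regmatches(header, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), header,
                                    ignore.case = TRUE))
    if (length(m) == 0L) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- get_int("NORB")
  nelec <- get_int("NELEC")
  ms2 <- get_int("MS2")
  if (is.na(norb) || norb < 1L)
    stop("malformed FCIDUMP header: NORB missing", call. = FALSE)
  t_one <- matrix(0, norb, norb)
  t_seen <- matrix(FALSE, norb, norb)
  v <- array(0, rep(norb, 4L))
  v_seen <- array(FALSE, rep(norb, 4L))
  core <- 0
  for (line in lines[-(1:hdr_end)]) {
    parts <- strsplit(line, "\\s+")[[1]]
    if (length(parts) != 5L)
      stop(sprintf("malformed FCIDUMP record: '%s'", line), call. = FALSE)
    val <- as.numeric(parts[1])
    idx <- as.integer(parts[2:5])
    if (anyNA(val) || anyNA(idx))
      stop(sprintf("malformed FCIDUMP record: '%s'", line), call. = FALSE)
    if (any(idx > norb) || any(idx < 0L))
      stop(sprintf("FCIDUMP index out of range in record '%s'", line),
           call. = FALSE)
    if (all(idx == 0L)) {
      core <- val
    } else if (idx[3] == 0L && idx[4] == 0L) {
      i <- idx[1]; j <- idx[2]
      if (i == 0L || j == 0L)
        stop(sprintf("FCIDUMP one-electron record with zero index: '%s'", line),
             call. = FALSE)
      for (p in list(c(i, j), c(j, i))) {
        if (t_seen[p[1], p[2]] && abs(t_one[p[1], p[2]] - val) > 1e-10)
          stop("duplicate inconsistent one-electron FCIDUMP records",
               call. = FALSE)
        t_one[p[1], p[2]] <- val
        t_seen[p[1], p[2]] <- TRUE
      }
    } else if (all(idx > 0L)) {
      i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
      perms <- list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
                    c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i))
      for (p in perms) {
        if (v_seen[p[1], p[2], p[3], p[4]] &&
            abs(v[p[1], p[2], p[3], p[4]] - val) > 1e-10)
          stop("duplicate inconsistent two-electron FCIDUMP records",
               call. = FALSE)
        v[p[1], p[2], p[3], p[4]] <- val
        v_seen[p[1], p[2], p[3], p[4]] <- TRUE
      }
    } else {
      stop(sprintf("FCIDUMP record with mixed zero indices: '%s'", line),
           call. = FALSE)
    }
  }
  integral_set(t_one, v, core_energy = core, n_electrons = nelec,
               ms2 = if (is.na(ms2)) 0L else ms2)
}

#' @rdname read_fcidump
#' @param integrals An [integral_set()].
#' @param n_electrons,ms2 Header overrides; default to the metadata stored
#'   on `integrals`.
#' @export
write_fcidump <- function(integrals, path, n_electrons = NULL, ms2 = NULL) {
  assert_integral_set(integrals)
  n <- integrals$n_orbitals
  nelec <- if (!is.null(n_electrons)) as.integer(n_electrons)
           else if (!is.na(integrals$n_electrons)) integrals$n_electrons
           else 0L
  ms2 <- if (!is.null(ms2)) as.integer(ms2) else integrals$ms2
  out <- c(
    sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, nelec, ms2),
    sprintf(" ORBSYM=%s", paste(rep("1,", n), collapse = "")),
    " ISYM=1,",
    "&END")
  fmt <- function(val, i, j, k, l)
    sprintf(" %23.16E %4d %4d %4d %4d", val, i, j, k, l)
  recs <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) for (l in seq_len(n)) {
    if (integrals$v_two[i, j, k, l] == 0) next
    ij <- if (i >= j) c(i, j) else c(j, i)
    kl <- if (k >= l) c(k, l) else c(l, k)
    if (ij[1] < kl[1] || (ij[1] == kl[1] && ij[2] < kl[2])) { tmp <- ij; ij <- kl; kl <- tmp }
    if (!(i == ij[1] && j == ij[2] && k == kl[1] && l == kl[2])) next
    recs <- c(recs, fmt(integrals$v_two[i, j, k, l], i, j, k, l))
  }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    if (integrals$t_one[i, j] != 0)
      recs <- c(recs, fmt(integrals$t_one[i, j], i, j, 0L, 0L))
  }
  if (integrals$core_energy != 0)
    recs <- c(recs, fmt(integrals$core_energy, 0L, 0L, 0L, 0L))
  writeLines(c(out, recs), path)
  invisible(path)
}
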