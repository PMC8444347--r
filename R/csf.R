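# Step-value encoding: integer codes 0,1,2,3 correspond to step values
# 0 (empty), u (singly occupied, spin-coupled up), d (singly occupied,
# spin-coupled down), 2 (doubly occupied).  The lexicographic basis order
# used throughout the package is 0 < u < d < 2, i.e. ascending codes.
STEP_CHARS <- c("0", "u", "d", "2")
STEP_OCC <- c(0L, 1L, 1L, 2L)
STEP_DB <- c(0L, 1L, -1L, 0L)   # change in b = 2S at each step

step_codes_from_chars <- function(x) {
  codes <- match(x, STEP_CHARS) - 1L
  if (anyNA(codes))
    stop("step values must be in {0, u, d, 2}", call. = FALSE)
  codes
}

#' Construct a configuration state function (CSF)
#'
#' A CSF is encoded by its step vector `d_k` over the spatial orbitals:
#' `0` (empty), `u` (singly occupied, coupling the cumulative spin up by
#' 1/2), `d` (singly occupied, coupling down by 1/2), `2` (doubly
#' occupied). The cumulative spin sequence `S_k` must stay non-negative and
#' end at the sector's total spin. The constructor errors on invalid input;
#' use [validate_step_vector()] for a non-throwing check that reports the
#' first violating position.
#'
#' @param steps Step vector: either a character vector with entries in
#'   `c("0","u","d","2")`, a single string such as `"u0udu0"`, or integer
#'   codes 0:3.
#' @param space A [spin_space()].
#' @return An object of class `"csf"` with fields `steps` (integer codes),
#'   `occ` (orbital occupations), `b` (cumulative `2 S_k` sequence) and
#'   `space`.
#' @examples
#' csf("ud", spin_space(2, 2, 0))
#' csf(c("u", "0", "u", "d", "u", "0"), spin_space(6, 4, 2))
#' @export
csf <- function(steps, space) {
  assert_spin_space(space)
  v <- validate_step_vector(steps, space)
  if (!v$valid)
    stop(sprintf("invalid step vector at position %d: %s", v$position, v$reason),
         call. = FALSE)
  v$csf
}

parse_steps <- function(steps) {
  if (is.character(steps)) {
    if (length(steps) == 1L && nchar(steps) > 1L)
      steps <- strsplit(steps, "")[[1]]
    step_codes_from_chars(steps)
  } else {
    codes <- as.integer(steps)
    if (anyNA(codes) || any(codes < 0L | codes > 3L))
      stop("integer step codes must be in 0:3", call. = FALSE)
    codes
  }
}

#' Validate a step vector against a spin sector
#'
#' Checks, position by position, that the cumulative spin never drops below
#' zero, and that the final electron count and total spin match the sector.
#'
#' @inheritParams csf
#' @return A list with elements `valid` (logical), `csf` (the constructed
#'   CSF when valid, else `NULL`), `position` (first violating orbital
#'   index, `NA` when valid) and `reason` (character).
#' @examples
#' validate_step_vector("du", spin_space(2, 2, 0))  # rejected at position 1
#' validate_step_vector("ud", spin_space(2, 2, 0))$csf
#' @export
validate_step_vector <- function(steps, space) {
  assert_spin_space(space)
  codes <- parse_steps(steps)
  n <- space$n_orbitals
  if (length(codes) != n)
    return(list(valid = FALSE, csf = NULL, position = NA_integer_,
                reason = sprintf("step vector has length %d, expected %d",
                                 length(codes), n)))
  b <- cumsum(STEP_DB[codes + 1L])
  neg <- which(b < 0L)
  if (length(neg) > 0L)
    return(list(valid = FALSE, csf = NULL, position = neg[1L],
                reason = "negative intermediate spin (d step without matching u)"))
  occ <- STEP_OCC[codes + 1L]
  if (sum(occ) != space$n_electrons)
    return(list(valid = FALSE, csf = NULL, position = n,
                reason = sprintf("electron count %d does not match N = %d",
                                 sum(occ), space$n_electrons)))
  if (b[n] != space$twice_S)
    return(list(valid = FALSE, csf = NULL, position = n,
                reason = sprintf("final 2S = %d does not match sector 2S = %d",
                                 b[n], space$twice_S)))
  x <- structure(
    list(steps = codes, occ = occ, b = b, space = space),
    class = "csf")
  list(valid = TRUE, csf = x, position = NA_integer_, reason = "ok")
}

is_csf <- function(x) inherits(x, "csf")

assert_csf <- function(x) {
  if (!is_csf(x)) stop("expected a `csf` object", call. = FALSE)
  invisible(x)
}

same_sector <- function(a, b) {
  identical(unclass(a$space), unclass(b$space))
}

#' @export
format.csf <- function(x, ...) {
  paste0("|", paste(STEP_CHARS[x$steps + 1L], collapse = ","), ">")
}

#' @export
print.csf <- function(x, ...) {
  cat(sprintf("<csf> %s  (S_k = %s)\n", format(x),
              paste(vapply(x$b, format_half_integer, ""), collapse = " ")))
  invisible(x)
}

csf_string <- function(x) paste(STEP_CHARS[x$steps + 1L], collapse = "")
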