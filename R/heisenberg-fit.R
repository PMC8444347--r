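# Mapping computed spin ladders onto (bi)quadratic Heisenberg models.
#
# For two sites A, B the coupling variable is
#   x(S) = [S(S+1) - S_A(S_A+1) - S_B(S_B+1)] / 2 = <S_A . S_B>,
# and the ladder of H = J S_A.S_B + J' (S_A.S_B)^2 is E(S) = J x + J' x^2.
# Fits act on spin gaps relative to the lowest-S state, which removes the
# constant term; J > 0 is antiferromagnetic.

heisenberg_x <- function(S, S_A, S_B) {
  (S * (S + 1) - S_A * (S_A + 1) - S_B * (S_B + 1)) / 2
}

#' Two-site Heisenberg model energies
#'
#' `E(S) = J x + J' x^2` with `x = [S(S+1) - S_A(S_A+1) - S_B(S_B+1)]/2`,
#' referenced to the lowest requested spin state. Reproduces the exact
#' two-site spin-model spectrum of [heisenberg_exact()] (the binding
#' oracle for the adopted closed form).
#'
#' @param S Vector of total spins, each within `|S_A - S_B| .. S_A + S_B`.
#' @param J Bilinear coupling.
#' @param J_biquadratic Biquadratic coupling.
#' @param S_A,S_B Site spins (default 5/2, the high-spin d^5 case).
#' @return A tibble with columns `S` and `energy` (gap to the lowest-S
#'   state).
#' @examples
#' model_energies(0:5, J = 1)   # Lande ladder, E(S) - E(0) = S (S + 1) / 2
#' @export
model_energies <- function(S, J, J_biquadratic = 0, S_A = 5/2, S_B = 5/2) {
  S <- as.numeric(S)
  if (any(S < abs(S_A - S_B) - 1e-9) || any(S > S_A + S_B + 1e-9))
    stop("total spin outside the coupling range of (S_A, S_B)", call. = FALSE)
  x <- heisenberg_x(S, S_A, S_B)
  e <- J * x + J_biquadratic * x^2
  ref <- which.min(S)
  tibble::tibble(S = S, energy = e - e[ref])
}

#' Fit a spin ladder to a Heisenberg model
#'
#' Ordinary least squares of the bilinear (`E = J x`) or biquadratic
#' (`E = J x + J' x^2`) two-site Heisenberg ladder to computed spin gaps
#' relative to the lowest-S state, plus the relative average error per
#' state omega of the fit.
#'
#' @param ladder A data frame with columns `S` and `energy` (one energy per
#'   total spin; any common reference).
#' @param model `"bilinear"` or `"biquadratic"`.
#' @param S_A,S_B Site spins (default 5/2).
#' @return An object of class `"heisenberg_fit"`: `J`, `J_biquadratic`
#'   (`NA` for the bilinear fit), `omega` (percent), `residuals` (tibble
#'   with per-state computed and model gaps), `model`, `S_A`, `S_B`.
#' @examples
#' lad <- model_energies(0:5, J = 1.44e-3)
#' fit_ladder(lad)            # recovers J, omega = 0
#' @export
fit_ladder <- function(ladder, model = c("bilinear", "biquadratic"),
                       S_A = 5/2, S_B = 5/2) {
  model <- match.arg(model)
  ladder <- tibble::as_tibble(ladder)
  if (!all(c("S", "energy") %in% names(ladder)))
    stop("`ladder` needs columns `S` and `energy`", call. = FALSE)
  ladder <- dplyr::arrange(ladder, .data$S)
  if (anyDuplicated(ladder$S))
    stop("one energy per total spin is required", call. = FALSE)
  n_par <- if (model == "bilinear") 1L else 2L
  if (nrow(ladder) < n_par + 1L)
    stop(sprintf("need at least %d states for a %s fit", n_par + 1L, model),
         call. = FALSE)
  x <- heisenberg_x(ladder$S, S_A, S_B)
  y <- ladder$energy - ladder$energy[1L]
  dx <- x - x[1L]
  dx2 <- x^2 - x[1L]^2
  keep <- -1L  # drop the reference row
  dat <- data.frame(y = y[keep], dx = dx[keep], dx2 = dx2[keep])
  if (all(abs(dat$dx) < 1e-12) && all(abs(dat$dx2) < 1e-12))
    stop("rank-deficient design: all states share the same coupling variable x",
         call. = FALSE)
  fit <- if (model == "bilinear") stats::lm(y ~ 0 + dx, data = dat)
         else stats::lm(y ~ 0 + dx + dx2, data = dat)
  cf <- stats::coef(fit)
  J <- unname(cf["dx"])
  Jp <- if (model == "biquadratic") unname(cf["dx2"]) else NA_real_
  me <- model_energies(ladder$S, J, if (is.na(Jp)) 0 else Jp, S_A, S_B)
  resid_tbl <- tibble::tibble(
    S = ladder$S, computed = y, model = me$energy,
    residual = y - me$energy)
  out <- structure(
    list(J = J, J_biquadratic = Jp, model = model, S_A = S_A, S_B = S_B,
         residuals = resid_tbl, ladder = ladder,
         omega = NA_real_),
    class = "heisenberg_fit")
  out$omega <- omega_error(ladder, me)
  out
}

#' Relative average error per state of a Heisenberg fit
#'
#' `omega = (100 / N) * sum_S |E_S^C - E_S^M| / dE_max^C` in percent, where
#' the sum runs over the `N` non-reference states (gaps relative to the
#' lowest-S state), `E^C` are the computed gaps, `E^M` the model gaps, and
#' `dE_max^C` is the computed gap between the highest- and lowest-spin
#' states.
#'
#' @param ladder Data frame with columns `S` and `energy` (computed).
#' @param model_ladder Data frame with columns `S` and `energy` (model),
#'   covering the same spins.
#' @return omega in percent (numeric scalar).
#' @export
omega_error <- function(ladder, model_ladder) {
  ladder <- dplyr::arrange(tibble::as_tibble(ladder), .data$S)
  model_ladder <- dplyr::arrange(tibble::as_tibble(model_ladder), .data$S)
  if (!identical(as.numeric(ladder$S), as.numeric(model_ladder$S)))
    stop("ladder and model must cover the same total spins", call. = FALSE)
  ec <- ladder$energy - ladder$energy[1L]
  em <- model_ladder$energy - model_ladder$energy[1L]
  de_max <- ec[length(ec)]
  if (abs(de_max) < 1e-300)
    stop("undefined omega: computed lowest-to-highest spin gap is zero",
         call. = FALSE)
  n_states <- length(ec) - 1L
  (100 / n_states) * sum(abs(ec - em)[-1L]) / abs(de_max)
}

#' Spin ladder of the complete-graph Heisenberg model
#'
#' For `n` equal spins `s` coupled with the same `J` on every pair,
#' `H = (J/2) [S_tot^2 - n s (s + 1)]`, so the ladder is
#' `E(S) = (J/2) [S(S+1) - n s (s+1)]` — e.g. the exact 4-site spin-5/2
#' ladder used for the tetrahedral cluster analysis.
#'
#' @param n_sites Number of sites.
#' @param s Site spin.
#' @param J Coupling (same on all pairs).
#' @return A tibble with columns `S` and `energy` for all total spins from
#'   the minimal one up to `n * s`.
#' @examples
#' complete_graph_ladder(4, 5/2, J = 1)  # S = 0 ... 10, gap 55 J
#' @export
complete_graph_ladder <- function(n_sites, s, J) {
  if (n_sites < 2L) stop("`n_sites` must be at least 2", call. = FALSE)
  tot2 <- round(2 * s * n_sites)
  S_min <- if (tot2 %% 2L == 0L) 0 else 1 / 2
  S <- seq(S_min, tot2 / 2, by = 1)
  tibble::tibble(S = S, energy = (J / 2) * (S * (S + 1) - n_sites * s * (s + 1)))
}

#' @export
print.heisenberg_fit <- function(x, ...) {
  cat(sprintf("<heisenberg_fit> %s model: J = %.6g", x$model, x$J))
  if (!is.na(x$J_biquadratic)) cat(sprintf(", J' = %.6g", x$J_biquadratic))
  cat(sprintf(", omega = %.4g%%\n", x$omega))
  invisible(x)
}

#' @export
tidy.heisenberg_fit <- function(x, ...) {
  tb <- tibble::tibble(term = "J", estimate = x$J)
  if (!is.na(x$J_biquadratic))
    tb <- dplyr::bind_rows(tb, tibble::tibble(term = "J_biquadratic",
                                              estimate = x$J_biquadratic))
  tb
}

#' @export
glance.heisenberg_fit <- function(x, ...) {
  tibble::tibble(model = x$model, J = x$J, J_biquadratic = x$J_biquadratic,
                 omega = x$omega, n_states = nrow(x$ladder),
                 S_A = x$S_A, S_B = x$S_B)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.heisenberg_fit <- function(object, ...) {
  dat <- object$residuals
  S_grid <- seq(min(dat$S), max(dat$S), length.out = 101)
  Jp <- if (is.na(object$J_biquadratic)) 0 else object$J_biquadratic
  x <- heisenberg_x(S_grid, object$S_A, object$S_B)
  x0 <- heisenberg_x(min(dat$S), object$S_A, object$S_B)
  curve <- tibble::tibble(
    S = S_grid,
    energy = object$J * (x - x0) + Jp * (x^2 - x0^2))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$S)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$energy),
                       color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$computed), size = 2) +
    ggplot2::labs(
      x = "total spin S", y = "E(S) - E(ref)",
      title = sprintf("%s Heisenberg fit: J = %.4g, omega = %.3g%%",
                      object$model, object$J, object$omega)) +
    ggplot2::theme_minimal()
}
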