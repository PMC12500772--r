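#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stability report
#'
#' @param x An `ma_stability` object.
#' @param ... Unused.
#' @return One row per eigenvalue: `eigenvalue` (complex), `modulus`.
#' @method tidy ma_stability
#' @export
tidy.ma_stability <- function(x, ...) {
  tibble::tibble(eigenvalue = x$eigenvalues, modulus = Mod(x$eigenvalues))
}

#' @rdname tidy.ma_stability
#' @method glance ma_stability
#' @export
glance.ma_stability <- function(x, ...) {
  tibble::tibble(trace = x$trace, det = x$det,
                 discriminant = x$discriminant,
                 label = x$label, matched_condition = x$matched_condition)
}

#' Tidy a flip-bifurcation report
#'
#' @param x An `ma_flip_report` object.
#' @param ... Unused.
#' @return One row per normal-form coefficient: `term`, `value`.
#' @method tidy ma_flip_report
#' @export
tidy.ma_flip_report <- function(x, ...) {
  tibble::tibble(term = names(x$coeffs),
                 value = unlist(x$coeffs, use.names = FALSE))
}

#' @rdname tidy.ma_flip_report
#' @method glance ma_flip_report
#' @export
glance.ma_flip_report <- function(x, ...) {
  tibble::tibble(tau_f = x$thresholds$tau_f,
                 tau_N = x$thresholds$tau_N,
                 tau_fbar = x$thresholds$tau_fbar,
                 matched_condition = x$matched_condition,
                 eta1 = x$eta1, eta2 = x$eta2, verdict = x$verdict)
}

#' Glance at a Turing report
#'
#' @param x An `ma_turing_report` object.
#' @param ... Unused.
#' @return One row: `tau_prime`, critical mode indices and Laplacian
#'   eigenvalue, and both closed-form reference quantities evaluated at
#'   the threshold.
#' @method glance ma_turing_report
#' @export
glance.ma_turing_report <- function(x, ...) {
  tibble::tibble(tau_prime = x$tau_prime,
                 critical_k = x$critical_mode[1],
                 critical_l = x$critical_mode[2],
                 critical_lambda = x$critical_lambda,
                 prop3_formula1 = x$prop3[["formula1"]],
                 prop3_formula2 = x$prop3[["formula2"]])
}
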