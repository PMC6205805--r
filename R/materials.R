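#' Material optical constants
#'
#' The complex refractive index of a material at the design energy is
#' `n = 1 - delta + i*beta`; `delta` drives phase shift and `beta`
#' absorption.
#'
#' @param delta refractive index decrement (dimensionless, >= 0).
#' @param beta absorption index (dimensionless, >= 0).
#' @param label material name.
#' @return an object of class `material_optics`.
#' @examples
#' material_optics(3.10e-7, 1.78e-10, "muscle @ 27.7 keV")
#' @export
material_optics <- function(delta, beta, label = "material") {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop_invalid("'delta' must be a single nonnegative number")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop_invalid("'beta' must be a single nonnegative number")
  structure(list(delta = delta, beta = beta, label = as.character(label)),
            class = "material_optics")
}

#' @export
print.material_optics <- function(x, ...) {
  cat(sprintf("material_optics: %s (delta = %.3g, beta = %.3g)\n",
              x$label, x$delta, x$beta))
  invisible(x)
}

# delta/beta of air and muscle tissue at the two design energies
.material_table <- list(
  murine = list(
    air = c(delta = 2.71e-10, beta = 1.42e-13),
    muscle = c(delta = 3.10e-07, beta = 1.78e-10)
  ),
  human = list(
    air = c(delta = 9.02e-11, beta = 4.27e-14),
    muscle = c(delta = 1.04e-07, beta = 5.07e-11)
  )
)
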