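# Physical constants (SI). Values fixed package-wide.
.kB <- 1.380649e-23   # Boltzmann constant, J/K
.mu0 <- 4 * pi * 1e-7 # vacuum permeability, N/A^2

#' Physical constants used throughout the package
#'
#' @return Named list with `k_B` (Boltzmann constant, J/K) and `mu_0`
#'   (vacuum permeability, N/A^2).
#' @export
#' @examples
#' physical_constants()$k_B
physical_constants <- function() {
  list(k_B = .kB, mu_0 = .mu0)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("nanotherm_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("`", name, "` must be a single positive finite number")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_invalid("`", name, "` must be a single non-negative finite number")
  }
  invisible(x)
}
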