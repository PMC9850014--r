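#' Piecewise-constant demography
#'
#' A demographic history as ordered epochs of constant diploid effective size,
#' in generations counted backwards from the present. The first epoch starts at
#' generation 0; epoch start times are strictly increasing, and the last epoch
#' extends indefinitely into the past.
#'
#' @param start numeric vector of epoch start times (generations backwards);
#'   first element must be 0, strictly increasing.
#' @param N integer vector of diploid effective sizes, one per epoch, all >= 2.
#' @param label optional text label.
#' @return An object of class \code{demography}.
#' @examples
#' # constant size 500
#' demography(0, 500)
#' # bottleneck at 40 generations, recovery 10 generations ago
#' demography(c(0, 10, 40), c(2000, 50, 5000))
#' @export
demography <- function(start, N, label = "") {
  start <- as.numeric(start)
  if (length(start) != length(N) || length(start) == 0)
    stop("invalid demography: start and N must have equal positive length")
  if (start[1] != 0) stop("invalid demography: first epoch must start at generation 0")
  if (length(start) > 1 && any(diff(start) <= 0))
    stop("invalid demography: epoch start times must be strictly increasing")
  if (any(is.na(N)) || any(N != round(N)) || any(N < 2))
    stop("invalid demography: all population sizes must be integers >= 2")
  structure(list(start = start, N = as.numeric(N), label = label),
            class = "demography")
}

#' @exportS3Method base::print
print.demography <- function(x, ...) {
  cat("demography", if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  for (i in seq_along(x$start)) {
    to <- if (i < length(x$start)) sprintf("%g", x$start[i + 1]) else "Inf"
    cat(sprintf("  [%g, %s) generations ago: N = %g\n", x$start[i], to, x$N[i]))
  }
  invisible(x)
}

#' Serial sampling scheme
#'
#' Diploid samples taken at one or more time points (generations backwards).
#' Lineages sampled at time t enter the coalescent process at t.
#'
#' @param time numeric vector of sampling times (generations backwards), distinct.
#' @param n_diploids integer vector of diploids sampled per event, all >= 1.
#' @param era character labels per event (e.g. "contemporary", "historical").
#' @return An object of class \code{sampling_scheme}.
#' @export
sampling_scheme <- function(time, n_diploids,
                            era = paste0("era", seq_along(time))) {
  time <- as.numeric(time)
  if (length(time) != length(n_diploids) || length(time) != length(era))
    stop("time, n_diploids and era must have equal length")
  if (anyDuplicated(time)) stop("sampling times must be distinct")
  if (any(time < 0)) stop("sampling times must be >= 0")
  if (any(n_diploids < 1) || any(n_diploids != round(n_diploids)))
    stop("n_diploids must be integers >= 1")
  if (sum(n_diploids) < 2) stop("total diploids sampled must be >= 2")
  structure(list(time = time, n_diploids = as.integer(n_diploids),
                 era = as.character(era)),
            class = "sampling_scheme")
}

#' @exportS3Method base::print
print.sampling_scheme <- function(x, ...) {
  cat("sampling scheme:\n")
  for (i in seq_along(x$time))
    cat(sprintf("  t = %g: %d diploids (%s)\n", x$time[i], x$n_diploids[i], x$era[i]))
  invisible(x)
}
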