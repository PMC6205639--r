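#' Horvitz-Thompson population size estimate
#'
#' The unbiased size estimator \eqn{\hat N = (T/t)^2 Q = Q/f}: each sampled
#' particle represents `1/f` particles because `f` is every particle's
#' inclusion probability under the uniform-random grid offset.
#'
#' @param Q total sampled count (>= 0).
#' @param grid a [quadrat_grid()].
#' @return The estimate, a numeric scalar.
#' @examples
#' g <- quadrat_grid(t = 20, period = 100)
#' estimate_size(50, g) # 25 * 50 = 1250
#' @export
estimate_size <- function(Q, grid) {
  .check_grid(grid)
  stopifnot(is.numeric(Q), all(Q >= 0))
  (grid$period / grid$t)^2 * Q
}

#' Protocol thresholds for the coefficient-of-error bands
#'
#' The advisory table mapping sample size Q and nonempty-quadrat count n to
#' the coefficient of error one can expect: counting roughly 50 particles in
#' 20 nonempty quadrats keeps the CE below about 15%, 100 in 30 below about
#' 10%, and 200 in 50 near 5%. The published thresholds are soft
#' ("approximately"); they are operationalized here as hard cutoffs and can
#' be overridden.
#'
#' @return Data frame with columns `band` (label), `Q` and `n` (minimum
#'   thresholds), ordered from loosest to tightest band.
#' @export
countem_bands <- function() {
  data.frame(band = c("15%", "10%", "5%"),
             Q = c(50, 100, 200),
             n = c(20, 30, 50),
             stringsAsFactors = FALSE)
}

.check_Qn <- function(Q, n) {
  stopifnot(is.numeric(Q), is.numeric(n), length(Q) == 1L, length(n) == 1L,
            Q >= 0, n >= 0)
  if (n > 0 && n > Q)
    stop("inconsistent sample: nonempty quadrats n cannot exceed Q",
         call. = FALSE)
}

#' Expected coefficient-of-error band for a sample
#'
#' Returns the tightest advisory band whose Q and n thresholds are both met
#' (see [countem_bands()]), or `"insufficient"` when even the loosest band's
#' thresholds fail.
#'
#' @param Q total sampled count.
#' @param n nonempty-quadrat count (n <= Q when n > 0).
#' @param bands threshold table, default [countem_bands()].
#' @return One of `"5%"`, `"10%"`, `"15%"`, `"insufficient"` — read as
#'   CE about 5%, below about 10%, below about 15%, or no guarantee.
#' @examples
#' ce_band(100, 30) # "10%"
#' ce_band(40, 18)  # "insufficient"
#' @export
ce_band <- function(Q, n, bands = countem_bands()) {
  .check_Qn(Q, n)
  met <- Q >= bands$Q & n >= bands$n
  if (!any(met)) "insufficient" else bands$band[max(which(met))]
}

#' Advice for reaching a target error band
#'
#' When the sample misses a target band, the remedy follows directly from the
#' \{f, n0\} parametrization: a low Q means the sampling fraction f is too
#' small (enlarge the quadrats relative to the period), while a low n means
#' too few quadrats cover the box (increase n0).
#'
#' @param Q,n as in [ce_band()].
#' @param target target band, one of `"15%"`, `"10%"` (default), `"5%"`.
#' @param bands threshold table, default [countem_bands()].
#' @return One of `"none"`, `"increase-f"`, `"increase-n0"`, `"both"`.
#' @examples
#' advise_sampling(40, 35, target = "10%")  # "increase-f"
#' advise_sampling(150, 12, target = "10%") # "increase-n0"
#' @export
advise_sampling <- function(Q, n, target = "10%", bands = countem_bands()) {
  .check_Qn(Q, n)
  target <- match.arg(target, bands$band)
  row <- bands[bands$band == target, ]
  low_Q <- Q < row$Q
  low_n <- n < row$n
  if (low_Q && low_n) "both"
  else if (low_Q) "increase-f"
  else if (low_n) "increase-n0"
  else "none"
}

#' Suggested starting sampling fraction
#'
#' A rough prior guess of the population's order of magnitude fixes a
#' sensible starting f (aiming at Q of about 100): populations up to about
#' a thousand call for f around 0.1 (for a few hundred particles quadrat
#' sampling barely pays off), thousands call for f around 0.04, and tens of
#' thousands or more for f around 0.01. With no guess at all, start from
#' n0 = 100 and f = 0.04 and adjust after a first pass.
#'
#' @param N optional numeric guess of the population size; classified into
#'   the magnitude classes below.
#' @param magnitude explicit class: `"unknown"` (default), `"small"`
#'   (N up to ~1e3), `"medium"` (~1e3-1e4), `"large"` (~1e4 and above).
#'   Ignored when `N` is given.
#' @return List with `f` and `n0` starting values.
#' @examples
#' suggest_initial_f(N = 5000)$f  # 0.04
#' suggest_initial_f()            # f = 0.04, n0 = 100
#' @export
suggest_initial_f <- function(N = NULL,
                              magnitude = c("unknown", "small", "medium",
                                            "large")) {
  magnitude <- match.arg(magnitude)
  if (!is.null(N)) {
    stopifnot(is.numeric(N), length(N) == 1L, N > 0)
    magnitude <- if (N <= 1e3) "small" else if (N <= 1e4) "medium" else "large"
  }
  f <- switch(magnitude, small = 0.1, medium = 0.04, large = 0.01,
              unknown = 0.04)
  list(f = f, n0 = 100)
}

#' One-shot population size estimation
#'
#' Runs the whole protocol once: build the grid from \{f, n0\}, superimpose
#' it uniformly at random, count with the forbidden-line rule, estimate
#' \eqn{\hat N = Q/f}, and report the expected error band plus parameter
#' advice. Warns when the mean count per nonempty quadrat exceeds 5 (crowded
#' quadrats make manual counting error-prone and inefficient; lower f).
#'
#' @param pattern a [point_pattern()].
#' @param f,n0 grid parametrization (defaults from [suggest_initial_f()]).
#' @param theta tilt angle in degrees (default 30).
#' @param seed optional seed for the random grid offset.
#' @param target target band passed to [advise_sampling()].
#' @return An object of class `"countem_estimate"`: list with `estimate`,
#'   `Q`, `n`, `band`, `advice`, `grid`, `f`, `n0`, `sample`.
#' @examples
#' bb <- bounding_box(640, 480)
#' est <- estimate_population(rpattern_uniform(1120, bb, seed = 1),
#'                            f = 0.09, n0 = 100, seed = 2)
#' est
#' @export
estimate_population <- function(pattern, f = 0.04, n0 = 100, theta = 30,
                                seed = NULL, target = "10%") {
  .check_pattern(pattern)
  grid <- quadrat_grid(f = f, n0 = n0, bbox = pattern$bbox, theta = theta)
  pl <- place_grid(grid, pattern$bbox, seed = seed)
  s <- sample_pattern(pattern, pl)
  if (s$n > 0 && s$Q / s$n > 5)
    warning(sprintf(
      "mean count per nonempty quadrat is %.1f (> 5); consider lowering f",
      s$Q / s$n), call. = FALSE)
  structure(list(estimate = estimate_size(s$Q, grid),
                 Q = s$Q, n = s$n,
                 band = ce_band(s$Q, s$n),
                 advice = advise_sampling(s$Q, s$n, target = target),
                 grid = grid, f = f, n0 = n0, sample = s),
            class = "countem_estimate")
}

#' @export
print.countem_estimate <- function(x, ...) {
  cat(sprintf("population size estimate: N-hat = %g\n", x$estimate))
  cat(sprintf("  sampled Q = %d in n = %d nonempty quadrats (f = %g, n0 = %g)\n",
              x$Q, x$n, x$f, x$n0))
  band <- if (x$band == "insufficient")
    "insufficient sample for an error guarantee"
  else sprintf("expected CE band: about %s or better", x$band)
  cat("  ", band, "\n", sep = "")
  if (x$advice != "none")
    cat("  advice: ", x$advice, "\n", sep = "")
  invisible(x)
}
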