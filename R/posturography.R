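#' Ellipse constant for the 95% confidence ellipse
#'
#' The square root of the 0.95 quantile of the chi-square distribution with
#' 2 degrees of freedom, `sqrt(-2*log(0.05)) = 2.4478...`. This is the
#' constant printed in the sway-area formula; the standard 95% ellipse area
#' uses its square (5.9915, the quantile itself).
#'
#' @return The constant, about 2.4478.
#' @examples
#' ellipse_constant()
#' ellipse_constant()^2  # chi-square 0.95 quantile, 2 df
#' @export
ellipse_constant <- function() sqrt(stats::qchisq(0.95, df = 2))

#' Sway area of a center-of-pressure recording
#'
#' Computes the area of the 95% confidence ellipse covering a 2-D
#' center-of-pressure (COP) trajectory, the standard posturographic balance
#' metric (smaller area = better balance). With `lambda1`, `lambda2` the
#' eigenvalues of the sample covariance of the (x, y) samples:
#'
#' * `as_printed`: `Area = pi * 2.4478 * sqrt(lambda1 * lambda2)` — the
#'   formula as conventionally printed with the chi-square constant applied
#'   once;
#' * `chi2_standard`: `Area = pi * 5.9915 * sqrt(lambda1 * lambda2)` — the
#'   dimensionally standard 95% ellipse area (chi-square quantile applied to
#'   the variance product).
#'
#' The two differ by the exact factor `2.4478`; every result records the
#' variant used.
#'
#' @param xy two-column numeric matrix (x, y) in cm, one row per sample.
#' @param variant `"as_printed"` (default) or `"chi2_standard"`.
#' @param denominator covariance denominator, `"n-1"` (unbiased, default)
#'   or `"n"`.
#' @return List of class `sway_result`: `area` (cm^2), `eigenvalues`
#'   (cm^2), `variant`, `n_samples`.
#' @examples
#' set.seed(1)
#' xy <- cbind(rnorm(500, sd = 0.8), rnorm(500, sd = 0.5))
#' sway_area(xy)$area
#' @export
sway_area <- function(xy, variant = c("as_printed", "chi2_standard"),
                      denominator = c("n-1", "n")) {
  variant <- match.arg(variant)
  denominator <- match.arg(denominator)
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("COP samples must be a two-column (x, y) matrix")
  if (nrow(xy) < 3L) stop("at least 3 COP samples required")
  if (any(!is.finite(xy))) stop("non-finite COP samples")
  n <- nrow(xy)
  S <- stats::cov(xy)
  if (denominator == "n") S <- S * (n - 1) / n
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)  # clip tiny negative rounding
  k <- ellipse_constant()
  if (variant == "chi2_standard") k <- k^2
  structure(list(area = pi * k * sqrt(prod(ev)), eigenvalues = ev,
                 variant = variant, n_samples = n),
            class = "sway_result")
}

#' @export
print.sway_result <- function(x, ...) {
  cat(sprintf("Sway area: %.4f cm^2 (%s, %d samples; eigenvalues %.4g, %.4g cm^2)\n",
              x$area, x$variant, x$n_samples,
              x$eigenvalues[1L], x$eigenvalues[2L]))
  invisible(x)
}

#' Aggregate per-trial sway areas into one balance score
#'
#' The balance performance parameter is the lower of the per-trial sway
#' areas (the better of the attempts); any number of successful trials >= 1
#' is accepted.
#'
#' @param areas numeric vector of per-trial sway areas (cm^2).
#' @return The minimum area; the number of trials is attached as the
#'   `n_trials` attribute.
#' @examples
#' balance_score(c(10.0, 12.0))
#' @export
balance_score <- function(areas) {
  areas <- as.numeric(areas)
  if (!length(areas)) stop("at least one successful trial required")
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("trial areas must be finite and non-negative")
  structure(min(areas), n_trials = length(areas))
}

#' Read a center-of-pressure recording
#'
#' Delimited text, either with header `t,x_cm,y_cm` (the `t` column is
#' dropped) or two headerless columns x, y with the sampling rate supplied
#' by the caller.
#'
#' @param path file path.
#' @param sampling_rate sampling rate in Hz (e.g. 4000 for a 4 kHz force
#'   plate); required when the file carries no time column.
#' @return List of class `cop_recording`: `xy` matrix (cm),
#'   `sampling_rate` (Hz).
#' @export
read_cop <- function(path, sampling_rate = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = has_header,
                           sep = detect_sep(path))
  if (has_header) {
    if (!all(c("x_cm", "y_cm") %in% names(tab)))
      stop("COP file header must provide x_cm and y_cm columns")
    if (is.null(sampling_rate) && "t" %in% names(tab) && nrow(tab) > 1L)
      sampling_rate <- 1 / stats::median(diff(tab$t))
    xy <- as.matrix(tab[, c("x_cm", "y_cm")])
  } else {
    if (ncol(tab) != 2L) stop("headerless COP file must have two columns")
    xy <- as.matrix(tab)
  }
  if (is.null(sampling_rate))
    stop("sampling_rate required when the file has no time column")
  dimnames(xy) <- NULL
  structure(list(xy = xy, sampling_rate = sampling_rate),
            class = "cop_recording")
}
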