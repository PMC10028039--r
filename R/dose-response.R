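# Four-parameter logistic viability fitting and combination-shift analysis.

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `r(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`
#' on the log-dose scale (the IC50 is fitted as `log(ic50)` for numerical
#' stability). Initialization is deterministic: top = max response,
#' bottom = min response, ic50 = geometric-mean dose, hill = 1. When
#' zero-dose (control) wells are present, responses are first normalized to
#' percent-of-control and the zero doses are excluded from the fit.
#'
#' @param plate `data.frame` with columns `dose` and `response` (viability;
#'   fraction or percent).
#' @param weighting `"relative"` (default) scales residuals by the model
#'   mean, the appropriate least-squares weighting for the roughly
#'   constant coefficient of variation of viability readouts; `"none"`
#'   fits unweighted absolute residuals.
#' @return An object of class `fit4pl`: list with `ic50`, `hill`, `top`,
#'   `bottom`, `rss` (unweighted residual sum of squares), `converged`,
#'   and `diagnostics` when not converged. Parameters are normalized so
#'   that `top > bottom` (the hill sign flips accordingly; positive hill =
#'   response falls with dose).
#' @examples
#' d <- 10^seq(-1, 3, length.out = 8)
#' fit_4pl(data.frame(dose = d, response = 100 / (1 + d / 10)))
#' @export
fit_4pl <- function(plate, weighting = c("relative", "none")) {
  stopifnot(all(c("dose", "response") %in% names(plate)))
  weighting <- match.arg(weighting)
  dose <- as.numeric(plate$dose)
  resp <- as.numeric(plate$response)
  if (any(!is.finite(resp))) stop("non-finite responses")
  if (any(dose < 0)) stop("negative doses")
  if (any(dose == 0)) {
    ctrl <- mean(resp[dose == 0])
    if (ctrl <= 0) stop("non-positive zero-dose control mean")
    resp <- resp / ctrl * 100
    resp <- resp[dose > 0]
    dose <- dose[dose > 0]
  }
  if (length(unique(dose)) < 4L)
    stop("need >= 4 distinct nonzero doses for a 4PL fit")
  if (stats::sd(resp) == 0) stop("no dose effect: responses are constant")
  ld <- log(dose)
  floor_w <- 1e-3 * max(abs(resp))  # keeps relative weights finite near 0
  model <- function(p)
    p[2] + (p[1] - p[2]) / (1 + exp(pmin(pmax(p[4] * (ld - p[3]), -700),
                                         700)))
  resid_plain <- function(p) model(p) - resp
  resid_rel <- function(p) {
    m <- model(p)
    (m - resp) / pmax(abs(m), floor_w)
  }
  start <- c(max(resp), min(resp), mean(ld), 1)
  ctl <- minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000)
  # the unweighted problem has the benign landscape; its solution then
  # seeds the relative-residual refinement
  fit <- tryCatch({
    f1 <- minpack.lm::nls.lm(par = start, fn = resid_plain, control = ctl)
    if (weighting == "relative")
      minpack.lm::nls.lm(par = f1$par, fn = resid_rel, control = ctl)
    else f1
  }, error = function(e) e)
  ok <- !inherits(fit, "error") && fit$info %in% 1:4
  if (!ok) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          diagnostics = if (inherits(fit, "error"))
                            conditionMessage(fit) else fit$message),
                     class = "fit4pl"))
  }
  p <- fit$par
  top <- p[1]; bottom <- p[2]; hill <- p[4]; ic50 <- exp(p[3])
  if (top < bottom) {  # same curve under (top,bottom,hill) -> (bottom,top,-hill)
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  structure(list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                 rss = sum((model(fit$par) - resp)^2),
                 converged = TRUE),
            class = "fit4pl")
}

#' @export
print.fit4pl <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf(
      "<fit4pl> ic50 = %.4g, hill = %.3g, top = %.4g, bottom = %.4g, rss = %.3g\n",
      x$ic50, x$hill, x$top, x$bottom, x$rss))
  } else {
    cat("<fit4pl> not converged:", x$diagnostics %||% "", "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Four-parameter logistic response curve
#'
#' @param dose dose vector.
#' @param ic50,hill,top,bottom curve parameters.
#' @return Expected responses.
#' @export
response_4pl <- function(dose, ic50, hill = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' IC50 shift between single-agent and combination plates
#'
#' Fits both plates and reports `ic50_mono / ic50_combo`; a ratio above 1
#' indicates potentiation by the combination partner.
#'
#' @param plate_mono,plate_combo plates as for [fit_4pl()].
#' @return List with `ratio`, `fit_mono`, `fit_combo`.
#' @export
ic50_shift <- function(plate_mono, plate_combo) {
  fm <- fit_4pl(plate_mono)
  fc <- fit_4pl(plate_combo)
  if (!isTRUE(fm$converged) || !isTRUE(fc$converged))
    stop("4PL fit did not converge for ",
         paste(c("mono", "combo")[!c(fm$converged, fc$converged)],
               collapse = " and "))
  list(ratio = fm$ic50 / fc$ic50, fit_mono = fm, fit_combo = fc)
}
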