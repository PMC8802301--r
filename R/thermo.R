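## Weighted least squares on an explicit design matrix. With known
## per-point sigmas the coefficient covariance is (X'WX)^-1 exactly; when
## unweighted it is the normal-equations inverse scaled by the residual
## variance (zero when the fit is saturated or exact).
.wls <- function(X, y, sigma = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (!is.null(sigma)) {
    if (length(sigma) != n || any(sigma <= 0))
      stop("per-point sigmas must be positive and match the points")
    w <- 1 / sigma
    Xw <- X * w; yw <- y * w
  } else {
    Xw <- X; yw <- y
  }
  qrX <- qr(Xw)
  if (qrX$rank < p) stop("singular design matrix")
  beta <- qr.coef(qrX, yw)
  XtXinv <- chol2inv(qr.R(qrX))
  if (!is.null(sigma)) {
    cov <- XtXinv
  } else {
    rss <- sum((y - X %*% beta)^2)
    s2 <- if (n > p) rss / (n - p) else 0
    cov <- s2 * XtXinv
  }
  list(coef = as.numeric(beta), cov = cov, df = n - p)
}

#' Quadratic fit of the contact-minimum free energy over temperature
#'
#' Fits `dF(T) = a + b*T + c*T^2` to contact-minimum depths across
#' temperatures, by weighted least squares when per-point standard errors
#' are supplied (weights `1/sigma^2`, covariance `(X'WX)^-1`) and ordinary
#' least squares otherwise (covariance scaled by the residual variance).
#' The curvature `c` carries the excess heat capacity; see [thermoState()].
#'
#' @param temperature K (at least 3 distinct values)
#' @param dF contact-minimum free energies, kcal/mol
#' @param sigma optional per-point standard errors, kcal/mol
#' @param ionicStrength ionic strength these points share, for bookkeeping
#' @return a \linkS4class{ThermoFit}
#' @examples
#' Ts <- c(273, 285, 298, 310, 323, 335, 348, 360, 373)
#' fit <- fitFreeEnergyVsTemperature(Ts, 2 - 0.02 * Ts - 3e-5 * Ts^2)
#' coef(fit)
#' @export
fitFreeEnergyVsTemperature <- function(temperature, dF, sigma = NULL,
                                       ionicStrength = NA_real_) {
  stopifnot(length(temperature) == length(dF))
  keep <- !is.na(dF)
  temperature <- temperature[keep]; dF <- dF[keep]
  if (!is.null(sigma)) sigma <- sigma[keep]
  if (length(unique(temperature)) < 3L)
    stop("fitFreeEnergyVsTemperature: need >= 3 distinct temperatures")
  ## fit on a centred/scaled basis (well conditioned), then map the
  ## coefficients and covariance back to the raw a + bT + cT^2 basis
  Tm <- mean(temperature)
  Ts <- stats::sd(temperature)
  if (Ts == 0) stop("fitFreeEnergyVsTemperature: degenerate temperatures")
  tt <- (temperature - Tm) / Ts
  X <- cbind(1, tt, tt^2)
  fit <- .wls(X, dF, sigma)
  J <- rbind(c(1, -Tm / Ts, (Tm / Ts)^2),
             c(0, 1 / Ts, -2 * Tm / Ts^2),
             c(0, 0, 1 / Ts^2))
  beta <- drop(J %*% fit$coef)
  cov <- J %*% fit$cov %*% t(J)
  new("ThermoFit",
      coef = stats::setNames(beta, c("a", "b", "c")),
      cov = (cov + t(cov)) / 2,
      nPoints = length(dF), conditionIS = as.numeric(ionicStrength),
      weighted = !is.null(sigma))
}

#' Excess thermodynamic quantities at one temperature
#'
#' Evaluates the excess free energy and its decomposition at temperature
#' `T` from a quadratic fit `dF(T) = a + b*T + c*T^2`:
#' \deqn{\Delta S = -\partial \Delta F/\partial T = -(b + 2cT),\quad
#'       \Delta U = \Delta F + T\Delta S = a - cT^2,\quad
#'       \Delta C_V = \partial \Delta U/\partial T = -2cT.}
#' Heat capacity is converted to cal mol^-1 K^-1. Standard errors come
#' from first-order propagation through the coefficient covariance. The
#' identity `dF = dU - T*dS` holds to machine precision by construction.
#'
#' @param fit a \linkS4class{ThermoFit}
#' @param temperature K (> 0)
#' @return a \linkS4class{ThermoState}
#' @examples
#' Ts <- c(273, 285, 298, 310, 323, 335, 348, 360, 373)
#' fit <- fitFreeEnergyVsTemperature(Ts, 2 - 0.02 * Ts - 3e-5 * Ts^2)
#' thermoState(fit, 298)
#' @export
thermoState <- function(fit, temperature) {
  stopifnot(is(fit, "ThermoFit"), temperature > 0)
  Tt <- temperature
  a <- fit@coef[["a"]]; b <- fit@coef[["b"]]; cc <- fit@coef[["c"]]
  dF <- a + b * Tt + cc * Tt^2
  dS <- -(b + 2 * cc * Tt)
  dU <- a - cc * Tt^2
  dCv <- kcalToCal(-2 * cc * Tt)
  propag <- function(g) sqrt(max(0, drop(t(g) %*% fit@cov %*% g)))
  new("ThermoState", temperature = Tt,
      dF = dF, dU = dU, dS = dS, dCv = dCv,
      dFerr = propag(c(1, Tt, Tt^2)),
      dUerr = propag(c(1, 0, -Tt^2)),
      dSerr = propag(c(0, -1, -2 * Tt)),
      dCverr = kcalToCal(propag(c(0, 0, -2 * Tt))))
}

#' Linear fit of the contact-minimum free energy over ionic strength
#'
#' Fits `dF(IS) = intercept + slope * IS` at one temperature; weighted when
#' sigmas are given. A negative slope reproduces salting-out: the contact
#' minimum deepens with added salt. With exactly two points and no weights
#' the fit is saturated: coefficients interpolate exactly, the
#' residual-based covariance is undefined (`NA`) and the result is flagged.
#'
#' @param ionicStrength mol/dm^3 (at least 2 distinct values)
#' @param dF contact-minimum free energies, kcal/mol
#' @param sigma optional per-point standard errors, kcal/mol
#' @param temperature K, for bookkeeping
#' @return an \linkS4class{IonicFit}
#' @examples
#' IS <- c(0, 0.4, 1, 1.5, 2)
#' coef(fitFreeEnergyVsIonicStrength(IS, -1.2 - 0.15 * IS, temperature = 298))
#' @export
fitFreeEnergyVsIonicStrength <- function(ionicStrength, dF, sigma = NULL,
                                         temperature = NA_real_) {
  stopifnot(length(ionicStrength) == length(dF))
  keep <- !is.na(dF)
  ionicStrength <- ionicStrength[keep]; dF <- dF[keep]
  if (!is.null(sigma)) sigma <- sigma[keep]
  if (length(unique(ionicStrength)) < 2L)
    stop("fitFreeEnergyVsIonicStrength: need >= 2 distinct ionic strengths")
  X <- cbind(1, ionicStrength)
  fit <- .wls(X, dF, sigma)
  saturated <- is.null(sigma) && length(dF) == 2L
  cov <- if (saturated) matrix(NA_real_, 2, 2) else (fit$cov + t(fit$cov)) / 2
  new("IonicFit", slope = fit$coef[2], intercept = fit$coef[1],
      cov = cov, conditionT = as.numeric(temperature),
      saturated = saturated)
}
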