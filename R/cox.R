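#' CoxModelFit: fitted Cox proportional-hazards model
#'
#' Container for a fitted (or published) multiple Cox proportional-hazards
#' model: coefficients on the log-hazard scale, their covariance matrix, and
#' the cohort size. Hazard ratios are \code{exp(coef)} exactly and Wald 95\%
#' confidence intervals for hazard ratios are \code{exp} of the coefficient
#' intervals.
#'
#' @slot coefficients Named numeric vector of log-hazard-ratio coefficients.
#' @slot vcov Covariance matrix of the coefficients.
#' @slot n Number of subjects.
#' @slot nEvents Number of observed events.
#' @slot ties Tie-handling method used by the fitter.
#'
#' @param object A \code{CoxModelFit}.
#' @param parm,level,... Passed as in \code{\link[stats]{confint}};
#'   \code{level} defaults to 0.95.
#'
#' @return \code{hazardRatios()} returns \code{exp(coef)};
#'   \code{confint()} a matrix of Wald confidence limits for the
#'   coefficients; \code{nEvents()} the event count.
#'
#' @aliases CoxModelFit hazardRatios nEvents coef,CoxModelFit-method
#'   vcov,CoxModelFit-method confint,CoxModelFit-method
#'   hazardRatios,CoxModelFit-method nEvents,CoxModelFit-method
#' @importFrom stats coef vcov confint
#' @exportClass CoxModelFit
setClass("CoxModelFit",
  slots = c(coefficients = "numeric", vcov = "matrix",
            n = "numeric", nEvents = "numeric", ties = "character"))

setValidity("CoxModelFit", function(object) {
  msg <- character()
  p <- length(object@coefficients)
  if (is.null(names(object@coefficients)))
    msg <- c(msg, "coefficients must be named")
  if (!all(dim(object@vcov) == c(p, p)))
    msg <- c(msg, "vcov dimensions must match coefficients")
  if (any(!is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname CoxModelFit-class
#' @export
setMethod("coef", "CoxModelFit", function(object) object@coefficients)

#' @rdname CoxModelFit-class
#' @export
setMethod("vcov", "CoxModelFit", function(object) object@vcov)

#' @rdname CoxModelFit-class
#' @export
setMethod("hazardRatios", "CoxModelFit", function(object) {
  exp(object@coefficients)
})

#' @rdname CoxModelFit-class
#' @export
setMethod("nEvents", "CoxModelFit", function(object) object@nEvents)

#' @rdname CoxModelFit-class
#' @export
setMethod("confint", "CoxModelFit",
  function(object, parm, level = 0.95, ...) {
    z <- qnorm(1 - (1 - level) / 2)
    se <- sqrt(diag(object@vcov))
    ci <- cbind(object@coefficients - z * se, object@coefficients + z * se)
    rownames(ci) <- names(object@coefficients)
    colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                               1 - (1 - level) / 2))
    if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
    ci
  })

setMethod("show", "CoxModelFit", function(object) {
  cat(sprintf("CoxModelFit (n = %d, %d events, ties = %s)\n",
              object@n, object@nEvents, object@ties))
  ci <- confint(object)
  hr <- hazardRatios(object)
  tab <- data.frame(coef = round(object@coefficients, 3),
                    HR = round(hr, 3),
                    `CI95 low` = round(exp(ci[, 1]), 3),
                    `CI95 high` = round(exp(ci[, 2]), 3),
                    check.names = FALSE)
  print(tab)
})

#' Fit a multiple Cox proportional-hazards model
#'
#' Fits a Cox model of overall survival on the given covariates using the
#' partial likelihood with Breslow tie handling (Efron available via
#' \code{ties}). The fit is delegated to \code{\link[survival]{coxph}};
#' coefficient confidence intervals are Wald intervals from the inverse
#' observed information.
#'
#' @param records Data frame with columns \code{time_months} (> 0),
#'   \code{event} (0/1) and one column per covariate. The conventional
#'   covariates are \code{age_decades}, \code{figo} (ordinal 0/1/2 for stages
#'   II/III/IV), \code{residual} (residual tumor yes=1/no=0), \code{grade}
#'   (grade 3 vs 2) and \code{predictor} (spread predictor, median-dichotomized
#'   or continuous).
#' @param covariates Character vector naming the covariate columns to enter.
#' @param ties Tie handling, \code{"breslow"} (default) or \code{"efron"}.
#'
#' @return A \code{\linkS4class{CoxModelFit}}.
#' @details A monotone partial likelihood (a covariate perfectly separating
#'   events) has no finite maximum; such fits are rejected with a diagnostic
#'   error rather than returned with divergent coefficients.
#' @seealso \code{\link{validateTransfer}}, \code{\link{hrWithinCI}},
#'   \code{\link{generateSurvival}}
#' @importFrom survival coxph Surv
#' @export
#' @examples
#' surv <- generateSurvival(n = 120, seed = 1)
#' fitCoxModel(surv)
fitCoxModel <- function(records,
                        covariates = c("age_decades", "figo", "residual",
                                       "grade", "predictor"),
                        ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  missing_cols <- setdiff(c("time_months", "event", covariates),
                          colnames(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  if (sum(records$event) < 1) stop("at least one event is required")
  if (any(records$time_months <= 0)) stop("times must be positive")
  X <- as.matrix(records[, covariates, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("covariates are collinear")
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(covariates, collapse = " + ")))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (monotone || any(abs(stats::coef(fit)) > 15))
    stop("monotone partial likelihood: a covariate perfectly separates ",
         "events; no finite coefficient exists")
  new("CoxModelFit",
      coefficients = stats::coef(fit),
      vcov = stats::vcov(fit),
      n = as.numeric(fit$n), nEvents = as.numeric(fit$nevent),
      ties = ties)
}

#' Construct a CoxModelFit from published summary statistics
#'
#' Builds a \code{\linkS4class{CoxModelFit}} from coefficients and 95\%
#' hazard-ratio confidence intervals as printed in a publication, with a
#' diagonal covariance matrix whose standard errors are recovered from the
#' interval widths (\code{se = log(hi/lo) / (2 z)}). Off-diagonal covariances
#' are unavailable from printed tables and set to zero.
#'
#' @param coefficients Named numeric vector of log-hazard-ratio coefficients.
#' @param hrCI Two-column matrix (low, high) of hazard-ratio CI95 limits,
#'   rows matching \code{coefficients}.
#' @param n,nEvents Cohort and event counts.
#' @return A \code{CoxModelFit}.
#' @seealso \code{\link{trainingSpreadModel}}
#' @export
coxModelFromSummary <- function(coefficients, hrCI, n, nEvents) {
  z <- qnorm(0.975)
  se <- log(hrCI[, 2] / hrCI[, 1]) / (2 * z)
  V <- diag(se^2, nrow = length(se))
  dimnames(V) <- list(names(coefficients), names(coefficients))
  new("CoxModelFit", coefficients = coefficients, vcov = V,
      n = as.numeric(n), nEvents = as.numeric(nEvents), ties = "breslow")
}

#' The published training-cohort Cox model
#'
#' The multiple Cox regression model of overall survival fitted on the
#' 165-patient training cohort (78 events): age in decades (coef 0.38), FIGO
#' stage as a single ordinal term IV vs III vs II (1.02), residual tumor yes
#' vs no (0.70), grade 3 vs 2 (0.54), and the median-dichotomized spread
#' predictor (0.56, HR 1.74, CI95 1.06-2.86). This is the model whose risk
#' scores are transferred to validation cohorts; its covariance matrix is
#' reconstructed (diagonal) from the printed confidence intervals.
#'
#' @return A \code{\linkS4class{CoxModelFit}} with five covariates.
#' @seealso \code{\link{validateTransfer}}, \code{\link{trainingCoxCoefficients}}
#' @export
#' @examples
#' hazardRatios(trainingSpreadModel())
trainingSpreadModel <- function() {
  cf <- trainingCoxCoefficients()
  ci <- rbind(age_decades = c(1.17, 1.81),
              figo        = c(1.63, 4.69),
              residual    = c(1.24, 3.30),
              grade       = c(0.95, 3.10),
              predictor   = c(1.06, 2.86))
  coxModelFromSummary(cf, ci, n = 165, nEvents = 78)
}

#' Training-cohort Cox coefficients
#'
#' The published log-hazard-ratio coefficients of the training-cohort
#' multiple Cox model, used as default planted effects by the survival
#' simulator.
#'
#' @return Named numeric vector (age_decades, figo, residual, grade,
#'   predictor).
#' @export
#' @examples
#' trainingCoxCoefficients()
trainingCoxCoefficients <- function() {
  c(age_decades = 0.38, figo = 1.02, residual = 0.70,
    grade = 0.54, predictor = 0.56)
}

#' Prognostic risk score under a Cox model
#'
#' Computes the linear predictor \code{sum(coef * covariate)} for new
#' subjects. No baseline hazard is involved; scores are relative log-hazards
#' and are used as transferred risk values in external validation.
#'
#' @param model A \code{\linkS4class{CoxModelFit}}.
#' @param newdata Data frame containing every model covariate.
#' @return Named numeric vector of risk scores, one per row of
#'   \code{newdata}.
#' @export
#' @examples
#' m <- trainingSpreadModel()
#' linearPredictor(m, data.frame(age_decades = 6, figo = 1, residual = 1,
#'                               grade = 1, predictor = 1))
linearPredictor <- function(model, newdata) {
  stopifnot(is(model, "CoxModelFit"))
  cf <- coef(model)
  missing_cols <- setdiff(names(cf), colnames(newdata))
  if (length(missing_cols))
    stop("newdata lacks covariate(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(newdata[, names(cf), drop = FALSE])
  lp <- drop(X %*% cf)
  names(lp) <- rownames(newdata)
  lp
}

#' Transfer validation of a Cox model on an external cohort
#'
#' Implements risk-transfer validation: the training model's risk score
#' (linear predictor) is computed for every validation subject and entered as
#' the single covariate of a new Cox model fitted on the validation cohort's
#' survival data. A well-calibrated transferred model has slope 1; the
#' validation is successful when the slope's 95\% confidence interval covers
#' 1.
#'
#' @param training A \code{\linkS4class{CoxModelFit}} fitted (or published)
#'   on the training cohort.
#' @param validation Data frame of validation-cohort records with
#'   \code{time_months}, \code{event} and every training covariate.
#' @return A list of class \code{"transferValidation"} with elements
#'   \code{slope} (calibration slope), \code{ci} (CI95), \code{pass}
#'   (\code{TRUE} iff the CI covers 1), and the univariate \code{fit}.
#' @export
#' @examples
#' train <- trainingSpreadModel()
#' val <- generateSurvival(n = 165, coefficients = coef(train), seed = 7)
#' validateTransfer(train, val)
validateTransfer <- function(training, validation) {
  stopifnot(is(training, "CoxModelFit"))
  if (sum(validation$event) < 1) stop("validation cohort has no events")
  risk <- linearPredictor(training, validation)
  dat <- data.frame(time_months = validation$time_months,
                    event = validation$event, risk = risk)
  fit <- fitCoxModel(dat, covariates = "risk")
  ci <- confint(fit)["risk", ]
  out <- list(slope = unname(coef(fit)["risk"]),
              ci = unname(ci),
              pass = ci[1] <= 1 && 1 <= ci[2],
              fit = fit)
  class(out) <- "transferValidation"
  out
}

#' @export
print.transferValidation <- function(x, ...) {
  cat(sprintf("Transfer validation: slope %.3f (CI95 %.3f-%.3f) -> %s\n",
              x$slope, x$ci[1], x$ci[2],
              if (x$pass) "PASS (CI covers 1)" else "FAIL"))
  invisible(x)
}

#' Hazard-ratio-within-CI validation check
#'
#' Checks whether the hazard ratio of a covariate estimated on the validation
#' cohort falls inside the 95\% confidence interval of the same covariate's
#' hazard ratio in the training model.
#'
#' @param validationModel,trainingModel \code{\linkS4class{CoxModelFit}}s.
#' @param covariate Name of the covariate; for the validation model the
#'   covariate holding the spread predictor may be named differently, so a
#'   pair \code{c(validation = "x", training = "y")} is also accepted.
#' @return \code{TRUE} iff the validation HR lies within the training CI95.
#' @export
hrWithinCI <- function(validationModel, trainingModel, covariate) {
  stopifnot(is(validationModel, "CoxModelFit"),
            is(trainingModel, "CoxModelFit"))
  if (length(covariate) == 2L && !is.null(names(covariate))) {
    cv <- covariate[["validation"]]; ct <- covariate[["training"]]
  } else {
    cv <- ct <- covariate
  }
  if (!cv %in% names(coef(validationModel)))
    stop("covariate '", cv, "' absent from validation model")
  if (!ct %in% names(coef(trainingModel)))
    stop("covariate '", ct, "' absent from training model")
  hr <- hazardRatios(validationModel)[[cv]]
  ci <- exp(confint(trainingModel)[ct, ])
  unname(ci[1] <= hr && hr <= ci[2])
}
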