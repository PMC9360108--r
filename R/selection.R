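# Model comparison (AIC, likelihood-ratio test) and stepwise covariate
# analysis with the standard pharmacometric link functions.

#' Akaike information criterion from an OFV
#'
#' `AIC = OFV + 2 npar`, with the OFV on the -2 log-likelihood scale
#' (excluding the n log(2pi) constant, so AICs are comparable across models
#' fitted to the same data).
#'
#' @param ofv objective function value.
#' @param npar number of estimated parameters (fixed effects + variance
#'   components + residual-error parameters).
#' @return Scalar AIC.
#' @export
aic <- function(ofv, npar) {
  if (npar < 0) stop("npar must be nonnegative")
  ofv + 2 * npar
}

#' Likelihood ratio test between nested models
#'
#' For a full model with `df` more parameters than the reduced model,
#' `dOFV = ofv_full - ofv_reduced` and the p-value comes from the
#' \eqn{\chi^2(df)} distribution on `-dOFV` (improvements make `dOFV`
#' negative; a nonnegative `dOFV` gives p = 1).
#'
#' @param ofv_full OFV of the larger model.
#' @param ofv_reduced OFV of the nested model.
#' @param df additional parameters in the full model (> 0).
#' @param alpha significance level.
#' @return List: `dofv`, `p`, `significant`.
#' @export
lrt <- function(ofv_full, ofv_reduced, df = 1, alpha = 0.05) {
  if (df <= 0) stop("df must be positive")
  dofv <- ofv_full - ofv_reduced
  p <- if (dofv < 0) stats::pchisq(-dofv, df, lower.tail = FALSE) else 1
  list(dofv = dofv, p = p, significant = p < alpha)
}

#' Model-development ladder of the reference single-dose imatinib analysis
#'
#' The candidate structural models (one- to three-compartment disposition
#' crossed with first-order, lagged, zero-order, double-peak and transit
#' absorption, then extra IIV terms and an omega block) with their reported
#' OFV and AIC values and parameter counts. Rows whose printed AIC is not
#' internally consistent with `OFV + 2 npar` (A2, and B3 which also reported
#' unrealistic estimates) are flagged `aic_consistent = FALSE`.
#'
#' @return Data frame with columns `model`, `description`, `iiv_on`, `npar`,
#'   `ofv`, `aic`, `aic_consistent`.
#' @export
model_ladder <- function() {
  path <- system.file("extdata", "model_ladder.csv", package = "transitpk",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# ---- covariate links ----------------------------------------------------

.link_forms <- c("linear", "power", "exponential", "hockey_stick",
                 "allometric", "proportional_shift")

#' Define a covariate-parameter link
#'
#' Multiplicative covariate effects on a typical value. Continuous forms are
#' referenced to the cohort median `reference` so the multiplier is 1 at the
#' reference; `hockey_stick` is a two-slope piecewise-linear form with its
#' break point at the median (continuous there by construction);
#' `allometric` uses a fixed exponent (0.75 for clearances, 1 for volumes,
#' by convention) unless `fixed = FALSE`; `proportional_shift` applies
#' `1 + theta` per non-reference category of a categorical covariate (each
#' extra level consumes one parameter, and `theta > -1` is enforced during
#' estimation).
#'
#' @param parameter structural parameter the effect acts on (e.g. `"cl"`).
#' @param covariate covariate column name in the dataset's covariate table.
#' @param form one of `"linear"`, `"power"`, `"exponential"`,
#'   `"hockey_stick"`, `"allometric"`, `"proportional_shift"`.
#' @param reference reference value: covariate median (continuous forms) or
#'   reference category (categorical).
#' @param theta_cov effect coefficient(s); length 2 for `hockey_stick`
#'   (slopes below/above the break), length (levels - 1) for
#'   `proportional_shift`, length 1 otherwise.
#' @param levels category levels for `proportional_shift` (reference first).
#' @param exponent allometric exponent when `form = "allometric"`.
#' @param fixed if `TRUE` the coefficients are not estimated (default only
#'   for allometric scaling).
#' @return Object of class `covariate_link`.
#' @export
covariate_link <- function(parameter, covariate, form, reference,
                           theta_cov = NULL, levels = NULL, exponent = NULL,
                           fixed = NULL) {
  form <- match.arg(form, .link_forms)
  if (form == "proportional_shift") {
    if (is.null(levels) || length(levels) < 2)
      stop("proportional_shift needs category levels (reference first)")
    if (is.null(theta_cov)) theta_cov <- rep(0, length(levels) - 1)
    if (length(theta_cov) != length(levels) - 1)
      stop("one coefficient per non-reference level")
    if (any(theta_cov <= -1)) stop("proportional shifts must exceed -1")
  } else if (form == "hockey_stick") {
    if (is.null(theta_cov)) theta_cov <- c(0, 0)
    if (length(theta_cov) != 2) stop("hockey_stick needs two slopes")
  } else if (form == "allometric") {
    if (is.null(exponent)) exponent <- if (parameter %in% c("cl", "q", "q3")) 0.75 else 1
    if (is.null(fixed)) fixed <- TRUE
    if (is.null(theta_cov)) theta_cov <- exponent
  } else {
    if (is.null(theta_cov)) theta_cov <- 0
    if (length(theta_cov) != 1) stop(form, " takes a single coefficient")
  }
  if (is.null(fixed)) fixed <- FALSE
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 reference = reference, theta_cov = theta_cov,
                 levels = levels, fixed = fixed),
            class = "covariate_link")
}

# multiplier applied to the typical value for a covariate value x
link_multiplier <- function(link, x) {
  th <- link$theta_cov
  switch(link$form,
    linear = max(1 + th * (x - link$reference), 1e-8),
    exponential = exp(th * (x - link$reference)),
    power = {
      if (x <= 0) stop("power link requires a positive covariate")
      (x / link$reference)^th
    },
    allometric = {
      if (x <= 0) stop("allometric link requires a positive covariate")
      (x / link$reference)^th
    },
    hockey_stick = {
      bp <- link$reference
      max(1 + th[1] * (min(x, bp) - bp) + th[2] * (max(x, bp) - bp), 1e-8)
    },
    proportional_shift = {
      i <- match(as.character(x), as.character(link$levels))
      if (is.na(i)) stop("unknown category '", x, "' for ", link$covariate)
      if (i == 1) 1 else max(1 + th[i - 1], 1e-8)
    })
}

#' Apply a covariate link to a typical value
#'
#' @param link a [covariate_link()].
#' @param typical_value the population typical value.
#' @param covariate_value the subject's covariate value.
#' @return Adjusted typical value (equals `typical_value` at the reference).
#' @export
apply_covariate_link <- function(link, typical_value, covariate_value) {
  typical_value * link_multiplier(link, covariate_value)
}

# ---- phenotype pooling --------------------------------------------------

#' Default diplotype-to-phenotype pooling map
#'
#' Pooling of pharmacogene diplotypes into phenotype groups for covariate
#' testing, following CPIC-style phenotype assignment: CYP3A4 normal
#' metabolisers (\*1/\*1) vs intermediate (\*1/\*20, \*1/\*22, \*22/\*22);
#' CYP3A5 expressers (\*1/\*3, IM) vs non-expressers (\*3/\*3, PM); CYP2C8
#' \*1/\*1 vs \*1/\*3 vs \*1/\*4-\*4/\*4; CYP2C9 NM (\*1/\*1) vs IM
#' (\*1/\*2, \*1/\*3, \*3/\*3); CYP2C19 NM (\*1/\*1) vs UM (\*1/\*17) vs
#' IM/PM (\*1/\*2, \*2/\*2); CYP2D6 NM (\*1/\*1) vs IM/PM (\*1/\*3, \*1/\*4,
#' \*1/\*5, \*4/\*5); CYP2B6 and ABCB1 genotypes are carried through as
#' genotype categories.
#'
#' @return Named list: locus -> named character vector (diplotype ->
#'   phenotype category).
#' @export
default_phenotype_map <- function() {
  list(
    CYP3A4 = c("*1/*1" = "NM", "*1/*20" = "IM", "*1/*22" = "IM", "*22/*22" = "IM"),
    CYP3A5 = c("*1/*3" = "IM", "*3/*3" = "PM", "*1/*1" = "NM"),
    CYP2C8 = c("*1/*1" = "NM", "*1/*3" = "IM3", "*1/*4" = "IM4", "*4/*4" = "IM4"),
    CYP2C9 = c("*1/*1" = "NM", "*1/*2" = "IM", "*1/*3" = "IM", "*3/*3" = "IM"),
    CYP2C19 = c("*1/*1" = "NM", "*1/*17" = "UM", "*1/*2" = "IM_PM", "*2/*2" = "IM_PM"),
    CYP2D6 = c("*1/*1" = "NM", "*1/*3" = "IM_PM", "*1/*4" = "IM_PM",
               "*1/*5" = "IM_PM", "*4/*5" = "IM_PM"),
    CYP2B6_G516T = c("GG" = "GG", "GT" = "GT", "TT" = "TT"),
    ABCB1_C3435T = c("CC" = "CC", "CT" = "CT", "TT" = "TT"))
}

#' Pool genotype calls into phenotype categories
#'
#' @param genotype_calls named character vector or one-row data frame of
#'   diplotypes per locus.
#' @param map pooling map as from [default_phenotype_map()].
#' @return Named character vector of phenotype categories; diplotypes absent
#'   from the map are returned as `"unclassified"` (never silently dropped).
#' @export
pool_phenotypes <- function(genotype_calls, map = default_phenotype_map()) {
  calls <- unlist(genotype_calls)
  out <- character(length(calls))
  names(out) <- names(calls)
  for (locus in names(calls)) {
    m <- map[[locus]]
    val <- if (!is.null(m)) unname(m[calls[[locus]]]) else NA_character_
    out[locus] <- if (is.na(val) || is.null(val)) "unclassified" else val
  }
  out
}

# ---- stepwise covariate scan -------------------------------------------

#' Stepwise covariate analysis (forward inclusion, backward elimination)
#'
#' Forward step: each remaining candidate link is added to the current model
#' and refitted; the candidate with the smallest likelihood-ratio p-value
#' below `forward_p` (df = number of added coefficients) is included, and
#' the process repeats. Backward step: each retained covariate is removed in
#' turn and is eliminated unless its removal gives p < `backward_p`. A
#' candidate whose refit fails the covariance step is skipped and logged in
#' the trace. The final model therefore never retains a covariate whose
#' backward p-value is at or above `backward_p`.
#'
#' @param ds a [pk_data()] with the candidate covariates present.
#' @param base_model a [poppk_model()] without the candidate links.
#' @param candidates list of [covariate_link()] objects to test.
#' @param forward_p forward inclusion significance level.
#' @param backward_p backward elimination significance level.
#' @param control a [poppk_control()] passed to the refits.
#' @param check_covariance require a successful covariance step for each
#'   candidate fit (skipped candidates are logged).
#' @return List: `model` (final fitted model), `fit` (final `poppk_fit`),
#'   `selected` (list of retained links), `trace` (data frame: step,
#'   candidate, form, dofv, df, p, decision).
#' @export
covariate_scan <- function(ds, base_model, candidates,
                           forward_p = 0.05, backward_p = 0.01,
                           control = poppk_control(),
                           check_covariance = TRUE) {
  fit0 <- fit_poppk(ds, base_model, control = control)
  if (check_covariance) {
    fit0 <- covariance_step(fit0)
    if (!isTRUE(fit0$covariance_ok))
      stop("base model failed the covariance step")
  }
  trace <- data.frame(step = character(), candidate = character(),
                      form = character(), dofv = numeric(), df = integer(),
                      p = numeric(), decision = character(),
                      stringsAsFactors = FALSE)
  label <- function(ln) paste0(ln$covariate, "->", ln$parameter)
  current_links <- list()
  current_fit <- fit0
  remaining <- candidates
  # forward inclusion
  repeat {
    if (!length(remaining)) break
    results <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      cand <- remaining[[i]]
      m <- base_model
      m$theta <- current_fit$model$theta
      m$iiv <- current_fit$model$iiv
      m$error <- current_fit$model$error
      m$covariate_links <- c(current_links, list(cand))
      f <- tryCatch(fit_poppk(ds, m, control = control),
                    error = function(e) NULL)
      ok <- !is.null(f)
      if (ok && check_covariance) {
        f <- covariance_step(f)
        ok <- isTRUE(f$covariance_ok)
      }
      df <- length(cand$theta_cov)
      if (!ok) {
        trace <- rbind(trace, data.frame(step = "forward", candidate = label(cand),
          form = cand$form, dofv = NA, df = df, p = NA, decision = "skipped"))
        results[[i]] <- list(ok = FALSE)
      } else {
        lr <- lrt(f$ofv, current_fit$ofv, df = df, alpha = forward_p)
        trace <- rbind(trace, data.frame(step = "forward", candidate = label(cand),
          form = cand$form, dofv = lr$dofv, df = df, p = lr$p,
          decision = if (lr$significant) "candidate" else "not significant"))
        results[[i]] <- list(ok = TRUE, fit = f, p = lr$p, sig = lr$significant)
      }
    }
    ps <- vapply(results, function(r) if (isTRUE(r$ok) && r$sig) r$p else Inf, 0)
    if (all(!is.finite(ps))) break
    best <- which.min(ps)
    current_fit <- results[[best]]$fit
    current_links <- c(current_links, list(remaining[[best]]))
    trace$decision[nrow(trace) - length(remaining) + best] <- "included"
    remaining <- remaining[-best]
  }
  # backward elimination
  repeat {
    if (!length(current_links)) break
    worst_p <- -Inf; worst <- 0; worst_fit <- NULL
    for (i in seq_along(current_links)) {
      m <- base_model
      m$theta <- current_fit$model$theta
      m$iiv <- current_fit$model$iiv
      m$error <- current_fit$model$error
      m$covariate_links <- current_links[-i]
      f <- fit_poppk(ds, m, control = control)
      df <- length(current_links[[i]]$theta_cov)
      lr <- lrt(current_fit$ofv, f$ofv, df = df, alpha = backward_p)
      trace <- rbind(trace, data.frame(step = "backward",
        candidate = label(current_links[[i]]), form = current_links[[i]]$form,
        dofv = lr$dofv, df = df, p = lr$p,
        decision = if (lr$p < backward_p) "retained" else "removed"))
      if (lr$p >= backward_p && lr$p > worst_p) {
        worst_p <- lr$p; worst <- i; worst_fit <- f
      }
    }
    if (worst == 0) break
    current_links <- current_links[-worst]
    current_fit <- worst_fit
  }
  list(model = current_fit$model, fit = current_fit,
       selected = current_links, trace = trace)
}
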