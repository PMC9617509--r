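#' One normalized inhibition curve
#'
#' Peak calcium-mobilization responses normalized so 1 is the uninhibited
#' VEGF response and 0 complete inhibition, measured over a concentration
#' series of one anti-VEGF agent.
#'
#' @param inhibitor_concs positive, sorted concentrations in nM.
#' @param responses normalized responses, same length.
#' @param replicate_id curve label.
#' @return An object of class `inhibition_curve`.
#' @export
inhibition_curve <- function(inhibitor_concs, responses,
                             replicate_id = "rep1") {
  check_positive(inhibitor_concs = inhibitor_concs)
  if (is.unsorted(inhibitor_concs)) {
    stop("'inhibitor_concs' must be sorted increasing", call. = FALSE)
  }
  if (length(responses) != length(inhibitor_concs)) {
    stop("'responses' and 'inhibitor_concs' must have equal length",
         call. = FALSE)
  }
  structure(list(inhibitor_concs = inhibitor_concs,
                 responses = as.numeric(responses),
                 replicate_id = as.character(replicate_id)),
            class = "inhibition_curve")
}

#' Four-parameter logistic IC50 fit
#'
#' Fits `response = bottom + (top - bottom) / (1 + (c / ic50)^hill)` by least
#' squares. Initialization is deterministic: `ic50` starts at the
#' concentration whose response is nearest the half-range, `hill` at 1 and
#' top/bottom at the response extremes; the Hill slope is bounded to
#' `[0.3, 5]` to keep degenerate data from producing pathological fits.
#'
#' @param curve an [inhibition_curve()], or a numeric concentration vector if
#'   `responses` is given.
#' @param responses responses when `curve` is a plain concentration vector.
#' @return An object of class `potency_fit`: `ic50` (nM), `hill`, `top`,
#'   `bottom`, `se_log_ic50` (natural-log scale), `df`, `residual_sum`.
#' @export
fit_4pl <- function(curve, responses = NULL) {
  if (!inherits(curve, "inhibition_curve")) {
    curve <- inhibition_curve(curve, responses)
  }
  conc <- curve$inhibitor_concs
  y <- curve$responses
  if (length(unique(conc)) < 5L) {
    stop("need at least 5 distinct concentrations", call. = FALSE)
  }
  if (stats::cor(log(conc), y) >= 0) {
    stop("fit error: responses do not decrease with concentration; ",
         "no inhibition to fit", call. = FALSE)
  }
  half <- (max(y) + min(y)) / 2
  start <- list(top = max(y), bottom = min(y),
                log_ic50 = log(conc[which.min(abs(y - half))]), hill = 1)
  lower <- c(top = -Inf, bottom = -Inf, log_ic50 = log(min(conc)) - 10,
             hill = 0.3)
  upper <- c(top = Inf, bottom = Inf, log_ic50 = log(max(conc)) + 10,
             hill = 5)
  form <- y ~ bottom + (top - bottom) / (1 + exp(hill * (log(conc) - log_ic50)))
  dat <- data.frame(conc = conc, y = y)
  fit <- tryCatch(
    stats::nls(form, data = dat, start = start, algorithm = "port",
               lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop("fit error: 4PL did not converge (no inflection in range?)",
             call. = FALSE)
      })
  }
  cf <- stats::coef(fit)
  if (cf[["bottom"]] >= cf[["top"]]) {
    stop("fit error: fitted curve is not inhibitory (bottom >= top)",
         call. = FALSE)
  }
  se <- tryCatch(sqrt(stats::vcov(fit)["log_ic50", "log_ic50"]),
                 error = function(e) NA_real_)
  structure(list(ic50 = exp(cf[["log_ic50"]]),
                 hill = cf[["hill"]],
                 top = cf[["top"]],
                 bottom = cf[["bottom"]],
                 se_log_ic50 = se,
                 df = length(y) - 4L,
                 residual_sum = sum(stats::resid(fit)^2)),
            class = "potency_fit")
}

#' @export
print.potency_fit <- function(x, ...) {
  cat(sprintf("<potency_fit> IC50 = %.4g nM (hill %.2f, top %.2f, bottom %.2f)\n",
              x$ic50, x$hill, x$top, x$bottom))
  invisible(x)
}

#' Tukey-adjusted pairwise comparison of fitted potencies
#'
#' All-pairs differences of log-IC50 with p-values adjusted by the
#' studentized-range distribution (Tukey). Replicate fits of the same agent
#' are combined by inverse-variance weighting of log-IC50; the studentized
#' range statistic is `q = sqrt(2) |d| / se_d`, so with two groups the
#' adjusted p equals the two-sided t-test p.
#'
#' @param fits list of [fit_4pl()] results (each must carry `se_log_ic50`).
#' @param agents character vector of agent labels, one per fit.
#' @return List with `table` (data.frame: pair, diff_log_ic50, se, q, p_adj)
#'   and `ordering` (agent labels sorted by increasing IC50).
#' @export
compare_potencies <- function(fits, agents) {
  stopifnot(length(fits) == length(agents), length(fits) >= 2L)
  se <- vapply(fits, `[[`, numeric(1), "se_log_ic50")
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("every fit must carry a finite positive 'se_log_ic50'",
         call. = FALSE)
  }
  lic <- vapply(fits, function(f) log(f$ic50), numeric(1))
  dfs <- vapply(fits, `[[`, integer(1), "df")
  groups <- split(seq_along(fits), agents)
  if (length(groups) < 2L) stop("need at least 2 agents", call. = FALSE)
  summ <- lapply(groups, function(ix) {
    w <- 1 / se[ix]^2
    list(mean = sum(w * lic[ix]) / sum(w),
         se = 1 / sqrt(sum(w)),
         df = sum(dfs[ix]))
  })
  k <- length(summ)
  nms <- names(summ)
  df_tot <- sum(vapply(summ, `[[`, numeric(1), "df"))
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  tab <- do.call(rbind, lapply(pairs, function(pr) {
    a <- summ[[pr[1L]]]; b <- summ[[pr[2L]]]
    d <- a$mean - b$mean
    sed <- sqrt(a$se^2 + b$se^2)
    q <- sqrt(2) * abs(d) / sed
    data.frame(pair = paste(pr, collapse = " - "),
               diff_log_ic50 = d, se = sed, q = q,
               p_adj = 1 - stats::ptukey(q, nmeans = k, df = df_tot))
  }))
  means <- vapply(summ, `[[`, numeric(1), "mean")
  list(table = tab, ordering = nms[order(means)])
}

#' Read inhibition curves from delimited text
#'
#' Expects columns `replicate_id`, `conc_nM`, `response`.
#'
#' @param path CSV file path.
#' @return List of [inhibition_curve()] objects.
#' @export
read_inhibition_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate_id", "conc_nM", "response")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("missing column '%s' in '%s'", miss[[1L]], path),
         call. = FALSE)
  }
  lapply(split(df, df$replicate_id), function(d) {
    d <- d[order(d$conc_nM), ]
    inhibition_curve(d$conc_nM, d$response, replicate_id = d$replicate_id[[1L]])
  })
}
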