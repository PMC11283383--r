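# Survival module: endpoint construction (TTNT, TTD), the counting-process
# representation for time-dependent covariates, the Kaplan-Meier
# product-limit estimator with Greenwood variance, and a Cox
# proportional-hazards fitter (Newton-Raphson on the partial likelihood,
# Efron or Breslow tie handling) over counting-process risk sets.

#' Time to next treatment (TTNT)
#'
#' Composite endpoint used as a proxy for progression-free survival: days
#' from index to the first dispensation of the next treatment or death,
#' whichever comes first; censored at the end of follow-up (end of study or
#' loss to follow-up).  An event on the index day is assigned time 0.5 so
#' that entry precedes exit.
#'
#' @param index_date index date.
#' @param next_treatment_date next-treatment date or `NA`.
#' @param death_date death date or `NA`.
#' @param followup_end end of follow-up.
#' @return list `time` (days), `event` (0/1).
#' @export
compute_ttnt <- function(index_date, next_treatment_date, death_date,
                         followup_end) {
  cand <- c(next_treatment_date, death_date)
  cand <- cand[!is.na(cand) & cand <= followup_end]
  if (length(cand)) {
    t <- as.numeric(min(cand) - index_date)
    ev <- 1L
  } else {
    t <- as.numeric(followup_end - index_date)
    ev <- 0L
  }
  if (t < 0) claims_abort("negative event time", "cllclaims_consistency_error")
  if (t == 0) t <- 0.5
  list(time = t, event = ev)
}

#' Time to permanent treatment discontinuation or death (TTD)
#'
#' As [compute_ttnt()], with the permanent-discontinuation date (coverage
#' end of the last regimen ending in discontinuation) in place of the next
#' treatment.
#'
#' @param index_date index date.
#' @param discontinuation_date discontinuation date or `NA`.
#' @param death_date death date or `NA`.
#' @param followup_end end of follow-up.
#' @return list `time` (days), `event` (0/1).
#' @export
compute_ttd <- function(index_date, discontinuation_date, death_date,
                        followup_end) {
  compute_ttnt(index_date, discontinuation_date, death_date, followup_end)
}

#' Expand endpoint rows to counting-process form
#'
#' Subjects hospitalized at time `h` before their exit are split into
#' `[0, h)` with `hosp_event = 0` and `[h, exit)` with `hosp_event = 1`;
#' covariate changes are left-continuous, so a hospitalization at the exit
#' time does not affect that exit's risk set.
#'
#' @param endpoints data.frame with columns `id`, `time`, `event` plus any
#'   fixed covariate columns.
#' @param hosp_times numeric vector of first-hospitalization times (days
#'   from index), `NA` when none, aligned with `endpoints` rows.
#' @return data.frame with columns `id`, `entry`, `exit`, `event`,
#'   `hosp_event` and the fixed covariates.
#' @export
to_counting_process <- function(endpoints, hosp_times) {
  stopifnot(nrow(endpoints) == length(hosp_times))
  covars <- setdiff(names(endpoints), c("id", "time", "event"))
  rows <- vector("list", nrow(endpoints))
  for (i in seq_len(nrow(endpoints))) {
    h <- hosp_times[i]
    t <- endpoints$time[i]
    ev <- endpoints$event[i]
    base <- endpoints[i, covars, drop = FALSE]
    if (!is.na(h) && h < t && h > 0) {
      r <- cbind(
        data.frame(id = rep(endpoints$id[i], 2), entry = c(0, h),
                   exit = c(h, t), event = c(0L, ev),
                   hosp_event = c(0L, 1L), stringsAsFactors = FALSE),
        base[c(1, 1), , drop = FALSE]
      )
    } else {
      hosp0 <- if (!is.na(h) && h <= 0) 1L else 0L
      r <- cbind(
        data.frame(id = endpoints$id[i], entry = 0, exit = t, event = ev,
                   hosp_event = hosp0, stringsAsFactors = FALSE),
        base
      )
    }
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' Computes S(t) = prod over event times t_i <= t of (1 - d_i / n_i), the
#' Greenwood variance, and the median survival time -- the smallest event
#' time with S(t) <= 0.5, absent ("not reached") when the curve never drops
#' to 0.5.
#'
#' @param time event/censoring times (> 0).
#' @param event 0 = censored, 1 = event.
#' @return object of class `"km_curve"`: data.frame `curve` (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `var_greenwood`, `se`),
#'   `median` (or `NA`), `n`, `n_events`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) {
    claims_abort("kaplan_meier requires at least one record",
                 "cllclaims_fit_error")
  }
  stopifnot(length(time) == length(event))
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0L) {
    curve <- data.frame(time = numeric(0), n_risk = numeric(0),
                        n_event = numeric(0), n_censor = numeric(0),
                        surv = numeric(0), var_greenwood = numeric(0),
                        se = numeric(0))
    return(structure(list(curve = curve, median = NA_real_, n = n,
                          n_events = 0L), class = "km_curve"))
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  cens <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  gw <- surv^2 * cumsum(d / (n_risk * (n_risk - d)))
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  structure(
    list(curve = data.frame(time = ut, n_risk = n_risk, n_event = d,
                            n_censor = cens, surv = surv,
                            var_greenwood = gw, se = sqrt(gw)),
         median = med, n = n, n_events = sum(d)),
    class = "km_curve"
  )
}

#' Survival probability from a Kaplan-Meier curve at given times
#'
#' Step-function evaluation: S is constant between event times and 1 before
#' the first.
#'
#' @param km a [kaplan_meier()] fit.
#' @param t numeric vector of times.
#' @return numeric vector of survival probabilities.
#' @export
km_prob <- function(km, t) {
  vapply(t, function(tt) {
    i <- findInterval(tt, km$curve$time)
    if (i == 0L) 1 else km$curve$surv[i]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n=%d, events=%d, median=%s\n", x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

# Precomputed geometry of the counting-process risk sets.  Risk-set sums at
# an event time t decompose as (prefix over entry < t) minus (prefix over
# exit < t), so all S0/S1/S2 sums are obtained from two cumulative-sum
# passes instead of per-time subsetting.
cox_prepare <- function(entry, exit, event, X) {
  p <- ncol(X)
  # packed design: [1, X, upper triangle of X x^T], scaled by exp(eta) later
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  XX <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  base <- cbind(1, X, XX)
  utimes <- sort(unique(exit[event == 1]))
  ord_exit <- order(exit)
  ord_entry <- order(entry)
  cnt_exit_lt <- findInterval(utimes, exit[ord_exit], left.open = TRUE)
  cnt_entry_lt <- findInterval(utimes, entry[ord_entry], left.open = TRUE)
  death_idx <- split(seq_along(exit)[event == 1],
                     match(exit[event == 1], utimes))
  death_idx <- death_idx[as.character(seq_along(utimes))]
  list(p = p, pairs = pairs, base = base, utimes = utimes,
       ord_exit = ord_exit, ord_entry = ord_entry,
       cnt_exit_lt = cnt_exit_lt, cnt_entry_lt = cnt_entry_lt,
       death_idx = death_idx)
}

unpack_sym <- function(v, p, pairs) {
  S2 <- matrix(0, p, p)
  S2[cbind(pairs[, 1], pairs[, 2])] <- v
  S2[cbind(pairs[, 2], pairs[, 1])] <- v
  S2
}

# Score vector, information matrix and log partial likelihood at beta.
cox_derivatives <- function(beta, X, prep, ties) {
  p <- prep$p
  eta <- drop(X %*% beta)
  w <- exp(eta)
  M <- prep$base * w
  pref_exit <- rbind(0, apply(M[prep$ord_exit, , drop = FALSE], 2, cumsum))
  pref_entry <- rbind(0, apply(M[prep$ord_entry, , drop = FALSE], 2, cumsum))

  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  i1 <- 2:(p + 1)
  i2 <- (p + 2):(1 + p + nrow(prep$pairs))
  for (k in seq_along(prep$utimes)) {
    S <- pref_entry[prep$cnt_entry_lt[k] + 1L, ] -
      pref_exit[prep$cnt_exit_lt[k] + 1L, ]
    S0 <- S[1]; S1 <- S[i1]; S2 <- unpack_sym(S[i2], p, prep$pairs)
    di <- prep$death_idx[[k]]
    d <- length(di)
    Xd <- X[di, , drop = FALSE]; wd <- w[di]
    loglik <- loglik + sum(eta[di])
    score <- score + colSums(Xd)
    if (ties == "efron" && d > 1L) {
      s0d <- sum(wd); s1d <- colSums(Xd * wd); s2d <- crossprod(Xd, Xd * wd)
    } else {
      s0d <- 0; s1d <- numeric(p); s2d <- matrix(0, p, p)
    }
    for (l in seq_len(d) - 1L) {
      f <- if (ties == "efron" && d > 1L) l / d else 0
      den <- S0 - f * s0d
      num <- S1 - f * s1d
      m <- num / den
      loglik <- loglik - log(den)
      score <- score - m
      info <- info + (S2 - f * s2d) / den - tcrossprod(m)
    }
  }
  list(loglik = loglik, score = score, info = info)
}

#' Cox proportional-hazards fit on counting-process data
#'
#' Maximizes the partial likelihood over counting-process risk sets (entry,
#' exit] by Newton-Raphson from beta = 0, with step-halving whenever a step
#' decreases the likelihood; convergence when the score sup-norm falls
#' below `tol`.  Efron tie handling by default (day-granularity claims
#' times are heavily tied); Breslow is available for cross-checks.
#' Standard errors come from the observed information; the score test at
#' beta = 0 is returned (for a single binary covariate without ties it
#' equals the log-rank statistic).
#'
#' @param data data.frame with columns `exit` (or `time`), `event`,
#'   optionally `entry` (default 0), and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol convergence tolerance on the score sup-norm (default 1e-9).
#' @param max_iter maximum Newton iterations (default 50).
#' @return object of class `"cox_fit"`: `coefficients` data.frame
#'   (`term`, `estimate`, `se`, `hr`, `ci_low`, `ci_high`, `p`),
#'   `loglik` (null, final), `score_test` (`chisq`, `df`, `p`), `iter`,
#'   `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  if (!"exit" %in% names(data) && "time" %in% names(data)) {
    data$exit <- data$time
  }
  if (!"entry" %in% names(data)) data$entry <- 0
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    claims_abort(sprintf("covariate column(s) not found: %s",
                         paste(missing_cov, collapse = ", ")),
                 "cllclaims_config_error")
  }
  n_events <- sum(data$event == 1)
  if (n_events == 0L) {
    claims_abort("no events in the data", "cllclaims_fit_error")
  }
  if (any(data$entry >= data$exit)) {
    claims_abort("entry time must precede exit time",
                 "cllclaims_validation_error")
  }
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    claims_abort(sprintf("degenerate (constant) covariate: %s",
                         paste(covariates[const], collapse = ", ")),
                 "cllclaims_fit_error")
  }
  # center covariates for numerical stability; estimates are unchanged
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)

  prep <- cox_prepare(data$entry, data$exit, data$event, Xc)

  p <- ncol(Xc)
  beta <- numeric(p)
  der <- cox_derivatives(beta, Xc, prep, ties)
  loglik0 <- der$loglik
  score0 <- der$score
  info0 <- der$info
  score_chisq <- tryCatch(
    drop(t(score0) %*% solve(info0, score0)),
    error = function(e) NA_real_
  )

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(der$info, der$score), error = function(e) NULL)
    if (is.null(step)) {
      claims_abort("singular information matrix in Cox fit",
                   "cllclaims_fit_error")
    }
    ll_tol <- 1e-9 * (abs(der$loglik) + 1)
    halving <- 0L
    repeat {
      beta_new <- beta + step
      der_new <- cox_derivatives(beta_new, Xc, prep, ties)
      if (is.finite(der_new$loglik) && der_new$loglik >= der$loglik - ll_tol) {
        break
      }
      halving <- halving + 1L
      if (halving > 20L) break
      step <- step / 2
    }
    delta_ll <- der_new$loglik - der$loglik
    delta_beta <- max(abs(beta_new - beta))
    beta <- beta_new
    der <- der_new
    if (any(abs(beta) > 15)) {
      worst <- covariates[which.max(abs(beta))]
      claims_abort(
        sprintf("monotone partial likelihood (possible separation) for covariate '%s'",
                worst),
        "cllclaims_fit_error"
      )
    }
    # converged on the score sup-norm, or on a numerically stationary
    # likelihood (the score cannot be driven below cancellation noise)
    if (max(abs(der$score)) < tol ||
        (iter > 1L && abs(delta_ll) < ll_tol && delta_beta < 1e-8)) {
      converged <- TRUE
      break
    }
  }

  vcov <- solve(der$info)
  se <- sqrt(diag(vcov))
  z <- beta / se
  coefs <- data.frame(
    term = covariates,
    estimate = unname(beta),
    se = unname(se),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta - 1.959963984540054 * se)),
    ci_high = exp(unname(beta + 1.959963984540054 * se)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefs, loglik = c(null = loglik0, final = der$loglik),
         vcov = vcov,
         score_test = list(chisq = score_chisq, df = p,
                           p = stats::pchisq(score_chisq, p,
                                             lower.tail = FALSE)),
         iter = iter, converged = converged,
         n = nrow(data), n_events = n_events, ties = ties),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n=%d, events=%d, ties=%s, iter=%d%s\n", x$n,
              x$n_events, x$ties, x$iter,
              if (x$converged) "" else " (NOT converged)"))
  co <- x$coefficients
  co$estimate <- round(co$estimate, digits)
  co$se <- round(co$se, digits)
  co$hr <- round(co$hr, digits)
  co$ci_low <- round(co$ci_low, digits)
  co$ci_high <- round(co$ci_high, digits)
  co$p <- signif(co$p, digits)
  print(co, row.names = FALSE)
  invisible(x)
}
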