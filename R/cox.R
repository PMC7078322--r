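#' Cox proportional-hazards regression
#'
#' Self-contained Newton–Raphson maximisation of the Cox partial
#' likelihood with Breslow (default) or Efron handling of tied event
#' times. Monotone likelihood (separation) is detected — coefficients
#' running away while the likelihood keeps creeping up — and returned as
#' a flagged fit rather than a silent huge coefficient.
#'
#' @param data A data frame of patient records.
#' @param time Column of follow-up times.
#' @param event Column of event flags (1 = death, 0 = censored).
#' @param covariates <[`tidy-select`][dplyr::dplyr_tidy_select]> covariate
#'   columns.
#' @param ties `"breslow"` or `"efron"`.
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `cox_fit` with coefficients, standard
#'   errors, hazard ratios with confidence intervals, Wald and
#'   likelihood-ratio p-values, and `converged`/`monotone` flags.
#'   `tidy()` gives the per-term table; `glance()` the model summary.
#' @export
#' @examples
#' df <- tibble::tibble(os = c(1, 2, 3, 4), death = 1, x = c(1, 0, 1, 0))
#' fit <- cox_fit(df, os, death, x)
#' tidy(fit)
cox_fit <- function(data, time, event, covariates,
                    ties = c("breslow", "efron"), conf_level = 0.95) {
  ties <- match.arg(ties)
  t <- pull_numeric(data, enquo(time), "data")
  d <- pull_numeric(data, enquo(event), "data")
  validate_surv(t, d)
  X <- dplyr::select(as_tibble(data), {{ covariates }})
  if (ncol(X) == 0) abort("At least one covariate is required.")
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  fit <- cox_engine(t, d, Xm, ties = ties)
  finalize_cox_fit(fit, colnames(X), ties, conf_level)
}

finalize_cox_fit <- function(fit, terms, ties, conf_level) {
  z_crit <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(fit$var))
  z <- fit$beta / se
  structure(
    list(
      terms = terms,
      coef = setNames(fit$beta, terms),
      se = setNames(se, terms),
      var = fit$var,
      hr = exp(fit$beta),
      ci_low = exp(fit$beta - z_crit * se),
      ci_high = exp(fit$beta + z_crit * se),
      z = z,
      p_wald = 2 * pnorm(-abs(z)),
      loglik_null = fit$loglik_null,
      loglik = fit$loglik,
      lr_stat = 2 * (fit$loglik - fit$loglik_null),
      lr_p = pchisq(2 * (fit$loglik - fit$loglik_null),
                    df = length(fit$beta), lower.tail = FALSE),
      n = fit$n, n_event = fit$n_event,
      ties = ties, conf_level = conf_level,
      converged = fit$converged, monotone = fit$monotone,
      iterations = fit$iterations
    ),
    class = "cox_fit"
  )
}

# Newton-Raphson maximiser of the Cox partial likelihood.  With
# `eval_only = TRUE` it just evaluates the log partial likelihood at
# `init` (or 0) without iterating.
cox_engine <- function(t, d, X, ties = "breslow", max_iter = 30,
                       tol = 1e-9, init = NULL, eval_only = FALSE) {
  n <- length(t)
  p <- ncol(X)
  if (sum(d) < 1) abort("Cox regression needs at least one event.")
  const <- apply(X, 2, function(x) diff(range(x)) == 0)
  if (any(const)) {
    abort(sprintf("Covariate `%s` is constant across subjects.",
                  colnames(X)[which(const)[1]] %||% which(const)[1]))
  }
  ord <- order(t)
  t <- t[ord]; d <- d[ord]; X <- X[ord, , drop = FALSE]
  # First index of each tie block (rows share the block's risk set).
  block_start <- match(t, t)
  ev <- which(d == 1)

  eval_pl <- function(beta) {
    eta <- drop(X %*% beta)
    eta <- eta - max(eta)                       # guard overflow
    w <- exp(eta)
    revcs <- function(x) rev(cumsum(rev(x)))
    S0 <- revcs(w)[block_start]
    S1 <- matrix(0, n, p)
    for (j in seq_len(p)) S1[, j] <- revcs(w * X[, j])[block_start]
    S2 <- array(0, c(n, p, p))
    for (j in seq_len(p)) {
      for (k in j:p) {
        v <- revcs(w * X[, j] * X[, k])[block_start]
        S2[, j, k] <- v
        S2[, k, j] <- v
      }
    }
    ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
    if (ties == "breslow") {
      ll <- sum(eta[ev]) - sum(log(S0[ev]))
      Ebar <- S1[ev, , drop = FALSE] / S0[ev]
      U <- colSums(X[ev, , drop = FALSE] - Ebar)
      for (j in seq_len(p)) {
        for (k in j:p) {
          val <- sum(S2[ev, j, k] / S0[ev] - Ebar[, j] * Ebar[, k])
          I[j, k] <- val; I[k, j] <- val
        }
      }
    } else {
      # Efron: within a tied block of dd events, the l-th event sees the
      # denominator reduced by l/dd of the tied events' own risk mass.
      ev_blocks <- split(ev, block_start[ev])
      for (rows in ev_blocks) {
        b <- block_start[rows[1]]
        dd <- length(rows)
        s0 <- S0[b]; s1 <- S1[b, ]; s2 <- S2[b, , ]
        if (p == 1) s2 <- matrix(s2, 1, 1)
        wD <- sum(w[rows])
        xD <- colSums(X[rows, , drop = FALSE] * w[rows])
        x2D <- matrix(0, p, p)
        for (j in seq_len(p)) {
          for (k in seq_len(p)) {
            x2D[j, k] <- sum(w[rows] * X[rows, j] * X[rows, k])
          }
        }
        ll <- ll + sum(eta[rows])
        for (l in seq_len(dd) - 1) {
          f <- l / dd
          s0l <- s0 - f * wD
          s1l <- s1 - f * xD
          s2l <- s2 - f * x2D
          ll <- ll - log(s0l)
          ebar <- s1l / s0l
          U <- U - ebar
          I <- I + s2l / s0l - outer(ebar, ebar)
        }
        U <- U + colSums(X[rows, , drop = FALSE])
      }
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- if (is.null(init)) numeric(p) else init
  res <- eval_pl(beta)
  if (eval_only) {
    return(list(beta = beta, loglik = res$ll, n = n, n_event = sum(d)))
  }
  converged <- FALSE
  monotone <- FALSE
  iter <- 0
  trace <- sprintf("iter 0: loglik %.6f", res$ll)
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(res$I, res$U), error = function(e) NULL)
    if (is.null(step)) {
      monotone <- TRUE
      break
    }
    new_beta <- beta + step
    new_res <- eval_pl(new_beta)
    halvings <- 0
    while (!is.finite(new_res$ll) || new_res$ll < res$ll - 1e-12) {
      halvings <- halvings + 1
      if (halvings > 25) break
      new_beta <- beta + (new_beta - beta) / 2
      new_res <- eval_pl(new_beta)
    }
    improved <- new_res$ll - res$ll
    beta <- new_beta
    res <- new_res
    trace <- c(trace, sprintf("iter %d: loglik %.6f beta %s", iter, res$ll,
                              paste(signif(beta, 6), collapse = ",")))
    if (max(abs(beta)) > 15) {
      monotone <- TRUE
      break
    }
    if (max(abs(res$U)) < 1e-8 || abs(improved) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !monotone) {
    abort(paste0("Cox fit did not converge in ", max_iter, " iterations:\n",
                 paste(trace, collapse = "\n")))
  }
  var <- tryCatch(solve(res$I), error = function(e) matrix(NA_real_, p, p))
  ll0 <- if (all(beta == 0)) res$ll else eval_pl(numeric(p))$ll
  list(beta = beta, var = var, loglik = res$ll, loglik_null = ll0,
       n = n, n_event = sum(d), converged = converged,
       monotone = monotone, iterations = iter)
}

# Score test of beta = 0 (used for the log-rank equivalence property).
cox_score_test <- function(t, d, x, ties = "breslow") {
  validate_surv(t, d)
  X <- matrix(as.numeric(x), ncol = 1)
  n <- length(t)
  ord <- order(t)
  t <- t[ord]; d <- d[ord]; X <- X[ord, , drop = FALSE]
  block_start <- match(t, t)
  ev <- which(d == 1)
  revcs <- function(z) rev(cumsum(rev(z)))
  w <- rep(1, n)
  S0 <- revcs(w)[block_start]
  S1 <- revcs(X[, 1])[block_start]
  S2 <- revcs(X[, 1]^2)[block_start]
  ebar <- S1[ev] / S0[ev]
  U <- sum(X[ev, 1] - ebar)
  I <- sum(S2[ev] / S0[ev] - ebar^2)
  U^2 / I
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n",
              x$n, x$n_event, x$ties,
              if (x$monotone) " [monotone likelihood]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method
tidy.cox_fit <- function(x, ...) {
  tibble(
    term = x$terms,
    estimate = unname(x$coef),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p_wald),
    hr = unname(x$hr),
    conf.low = unname(x$ci_low),
    conf.high = unname(x$ci_high)
  )
}

#' @exportS3Method
glance.cox_fit <- function(x, ...) {
  tibble(
    n = x$n, n_event = x$n_event,
    loglik = x$loglik, loglik_null = x$loglik_null,
    lr_stat = x$lr_stat, lr_p = x$lr_p,
    ties = x$ties, converged = x$converged, monotone = x$monotone
  )
}

#' Forward stepwise Cox model selection
#'
#' Forward stepwise selection with elimination, in the "Forward: LR"
#' convention: at each step the candidate with the smallest
#' likelihood-ratio entry p-value is added if it is below `p_in`; after
#' every entry, included variables whose likelihood-ratio removal
#' p-value exceeds `p_out` are removed (largest first); the procedure
#' stops at a fixpoint. Ties break towards the earlier candidate in the
#' given order. An empty selection is a valid outcome.
#'
#' @inheritParams cox_fit
#' @param candidates <[`tidy-select`][dplyr::dplyr_tidy_select]> candidate
#'   covariate columns, in priority order.
#' @param p_in Entry threshold (default 0.05).
#' @param p_out Removal threshold (default 0.10).
#' @return A list of class `stepwise_cox`: `selected` (character vector,
#'   possibly empty), `fit` (the final `cox_fit`, or `NULL` if empty) and
#'   `trace` (tibble of entry/removal steps).
#' @export
stepwise_cox <- function(data, time, event, candidates,
                         p_in = 0.05, p_out = 0.10,
                         ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  t <- pull_numeric(data, enquo(time), "data")
  d <- pull_numeric(data, enquo(event), "data")
  validate_surv(t, d)
  X <- dplyr::select(as_tibble(data), {{ candidates }})
  if (ncol(X) == 0) abort("At least one candidate is required.")
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  cand <- colnames(X)

  loglik_of <- function(vars) {
    if (length(vars) == 0) {
      # Null model log partial likelihood (beta = 0).
      fit0 <- cox_engine(t, d, Xm[, cand[1], drop = FALSE], ties = ties,
                         init = 0, eval_only = TRUE)
      return(fit0$loglik)
    }
    cox_engine(t, d, Xm[, vars, drop = FALSE], ties = ties)$loglik
  }

  selected <- character(0)
  trace <- list()
  ll_current <- loglik_of(selected)
  repeat {
    changed <- FALSE
    # Entry step.
    pool <- setdiff(cand, selected)
    if (length(pool) > 0) {
      entry_p <- vapply(pool, function(v) {
        ll <- tryCatch(loglik_of(c(selected, v)), error = function(e) NA_real_)
        if (is.na(ll)) return(NA_real_)
        pchisq(2 * (ll - ll_current), df = 1, lower.tail = FALSE)
      }, numeric(1))
      ok <- which(!is.na(entry_p) & entry_p < p_in)
      if (length(ok) > 0) {
        pick <- pool[ok[which.min(entry_p[ok])]]
        selected <- c(selected, pick)
        ll_current <- loglik_of(selected)
        trace[[length(trace) + 1]] <- tibble(
          step = length(trace) + 1L, action = "add", term = pick,
          p = min(entry_p[ok])
        )
        changed <- TRUE
      }
    }
    # Removal step(s).
    repeat {
      if (length(selected) == 0) break
      removal_p <- vapply(selected, function(v) {
        ll <- loglik_of(setdiff(selected, v))
        pchisq(2 * (ll_current - ll), df = 1, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(removal_p)
      if (removal_p[worst] > p_out) {
        out <- selected[worst]
        selected <- setdiff(selected, out)
        ll_current <- loglik_of(selected)
        trace[[length(trace) + 1]] <- tibble(
          step = length(trace) + 1L, action = "remove", term = out,
          p = removal_p[worst]
        )
        changed <- TRUE
      } else {
        break
      }
    }
    if (!changed || length(trace) > 4 * length(cand) + 8) break
  }

  fit <- if (length(selected) > 0) {
    finalize_cox_fit(
      cox_engine(t, d, Xm[, selected, drop = FALSE], ties = ties),
      selected, ties, 0.95
    )
  } else {
    NULL
  }
  structure(
    list(selected = selected, fit = fit,
         trace = if (length(trace)) dplyr::bind_rows(trace) else
           tibble(step = integer(), action = character(),
                  term = character(), p = numeric())),
    class = "stepwise_cox"
  )
}

#' @export
print.stepwise_cox <- function(x, ...) {
  cat("<stepwise_cox> selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}
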