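#' Stepwise discriminant function analysis (Wilks'-lambda criterion)
#'
#' Selects acoustic features for discriminating individuals by the classic
#' stepwise procedure: at each step the partial F of adding each candidate
#' (or removing each entered feature) given the current set is computed from
#' the ratio of Wilks' lambdas; the candidate with the smallest
#' probability-of-F enters if p < `p_in`, and the entered feature with the
#' largest probability leaves if p > `p_out`. The procedure stops when
#' neither rule applies.
#'
#' With `S` the current set of size `p`, `N` calls and `g` groups, the
#' F-to-enter of candidate `x` is
#' `F = ((N - g - p) / (g - 1)) * (lambda(S) / lambda(S + x) - 1)` with
#' `(g - 1, N - g - p)` degrees of freedom, where `lambda(S)` is the ratio of
#' the within-group to total scatter determinants over `S`. Ties in p are
#' broken by the larger partial F, then by column order.
#'
#' @param features Call-level feature table: one row per call, an
#'   `individual` column, numeric feature columns.
#' @param individual Name of the grouping column.
#' @param p_in Probability-of-F to enter (must be <= `p_out`).
#' @param p_out Probability-of-F to remove.
#' @param cond_tol Condition-number threshold above which a candidate's
#'   within-group scatter is treated as rank deficient and the candidate is
#'   skipped (the decision is logged in the model's `skipped` field).
#' @return An object of class `stepwise_dfa` with the selected features (in
#'   entry order), the full entry/removal trace, group means, pooled
#'   within-group covariance of the selected features, canonical
#'   coefficients, and the model dimensions `N`, `g`, `p`, `n_i`. An empty
#'   selection (no feature qualifies at step 1) is returned flagged, not as
#'   an error.
#' @export
dfa_stepwise <- function(features, individual = "individual",
                         p_in = 0.05, p_out = 0.10, cond_tol = 1e12) {
  p_in <- check_prob(p_in, "p_in")
  p_out <- check_prob(p_out, "p_out")
  if (p_in > p_out) abort("`p_in` must be <= `p_out` (guards entry/removal cycles).")
  cols <- validate_features(features, individual)
  X <- as.matrix(features[cols])
  grp <- factor(features[[individual]])
  N <- nrow(X); g <- nlevels(grp); K <- ncol(X)
  n_i <- as.integer(table(grp))

  # Total and within-group scatter of all candidate features.
  Tm <- crossprod(sweep(X, 2, colMeans(X)))
  gm <- rowsum(X, grp) / n_i
  Wm <- crossprod(X - gm[as.integer(grp), , drop = FALSE])

  lambda_of <- function(S) {
    if (length(S) == 0L) return(1)
    exp(logdet_psd(Wm[S, S, drop = FALSE]) - logdet_psd(Tm[S, S, drop = FALSE]))
  }

  selected <- integer(0)
  sk_step <- integer(0); sk_feature <- character(0); sk_reason <- character(0)
  log_skip <- function(step, feature, reason) {
    sk_step <<- c(sk_step, step)
    sk_feature <<- c(sk_feature, feature)
    sk_reason <<- c(sk_reason, reason)
  }
  tr_step <- integer(0); tr_action <- character(0); tr_feature <- character(0)
  tr_f <- double(0); tr_p <- double(0); tr_lambda <- double(0)
  log_trace <- function(step, action, feature, partial_f, p_value, lambda) {
    tr_step <<- c(tr_step, step)
    tr_action <<- c(tr_action, action)
    tr_feature <<- c(tr_feature, feature)
    tr_f <<- c(tr_f, partial_f)
    tr_p <<- c(tr_p, p_value)
    tr_lambda <<- c(tr_lambda, lambda)
  }
  step <- 0L
  lambda_cur <- 1
  repeat {
    step <- step + 1L
    if (step > 3L * K) break
    p_cur <- length(selected)
    df2 <- N - g - p_cur
    if (df2 < 1L) break

    # --- entry phase -----------------------------------------------------
    cand <- setdiff(seq_len(K), selected)
    best <- NULL
    for (x in cand) {
      if (Tm[x, x] <= 0) {
        log_skip(step, cols[x], "zero total variance")
        next
      }
      # Tolerance check: within-group variance of x conditional on the
      # selected set. A near-zero remainder relative to the marginal
      # variance means collinearity with features already entered.
      if (Wm[x, x] > 0) {
        w_cond <- if (p_cur == 0L) Wm[x, x] else {
          Wm[x, x] - drop(Wm[x, selected, drop = FALSE] %*%
                            solve(Wm[selected, selected, drop = FALSE],
                                  Wm[selected, x, drop = FALSE]))
        }
        if (w_cond / Wm[x, x] < 1 / cond_tol) {
          log_skip(step, cols[x], "rank-deficient within-group scatter")
          next
        }
      }
      lam_x <- lambda_of(c(selected, x))
      if (lam_x <= 0) {
        # Zero within-group variance with distinct means: infinite partial F.
        Fx <- Inf; px <- 0; lam_x <- 0
      } else {
        Fx <- max((df2 / (g - 1)) * (lambda_cur / lam_x - 1), 0)
        px <- pf(Fx, g - 1, df2, lower.tail = FALSE)
      }
      if (is.null(best) || px < best$p - 1e-12 ||
          (abs(px - best$p) <= 1e-12 && Fx > best$F)) {
        best <- list(x = x, F = Fx, p = px, lambda = lam_x)
      }
    }
    entered <- FALSE
    if (!is.null(best) && best$p < p_in) {
      selected <- c(selected, best$x)
      lambda_cur <- best$lambda
      log_trace(step, "enter", cols[best$x], best$F, best$p, lambda_cur)
      entered <- TRUE
    }

    # --- removal phase ---------------------------------------------------
    if (entered && length(selected) > 1L) {
      repeat {
        p_now <- length(selected)
        df2r <- N - g - (p_now - 1L)
        worst <- NULL
        # Never reconsider the feature entered this step (cycle guard).
        removable <- selected[selected != best$x]
        for (x in removable) {
          Srm <- setdiff(selected, x)
          lam_rm <- lambda_of(Srm)
          if (lambda_cur <= 0) { Fx <- Inf; px <- 0 }
          else {
            Fx <- (df2r / (g - 1)) * (lam_rm / lambda_cur - 1)
            Fx <- max(Fx, 0)
            px <- pf(Fx, g - 1, df2r, lower.tail = FALSE)
          }
          if (is.null(worst) || px > worst$p + 1e-12 ||
              (abs(px - worst$p) <= 1e-12 && Fx < worst$F)) {
            worst <- list(x = x, F = Fx, p = px, lambda = lam_rm)
          }
        }
        if (is.null(worst) || worst$p <= p_out) break
        selected <- setdiff(selected, worst$x)
        lambda_cur <- worst$lambda
        log_trace(step, "remove", cols[worst$x], worst$F, worst$p, lambda_cur)
        if (length(selected) <= 1L) break
      }
    }
    if (!entered) break
    # Perfect separation: the Wilks' lambda cannot improve further and
    # subsequent partial-F ratios are undefined.
    if (lambda_cur <= 0) break
  }

  sel_cols <- cols[selected]
  p_sel <- length(selected)
  group_means <- pooled_cov <- canonical <- NULL
  if (p_sel > 0L) {
    group_means <- gm[, selected, drop = FALSE]
    colnames(group_means) <- sel_cols
    pooled_cov <- Wm[selected, selected, drop = FALSE] / (N - g)
    dimnames(pooled_cov) <- list(sel_cols, sel_cols)
    Bm <- (Tm - Wm)[selected, selected, drop = FALSE]
    canonical <- tryCatch({
      ev <- eigen(solve(Wm[selected, selected, drop = FALSE], Bm))
      m <- min(g - 1L, p_sel)
      cf <- Re(ev$vectors[, seq_len(m), drop = FALSE])
      rownames(cf) <- sel_cols
      colnames(cf) <- paste0("LD", seq_len(m))
      cf
    }, error = function(e) NULL)
  }

  structure(
    list(
      selected = sel_cols,
      trace = tibble::tibble(step = tr_step, action = tr_action,
                             feature = tr_feature, partial_f = tr_f,
                             p_value = tr_p, wilks_lambda = tr_lambda),
      skipped = tibble::tibble(step = sk_step, feature = sk_feature,
                               reason = sk_reason),
      empty = p_sel == 0L,
      group_means = group_means,
      pooled_cov = pooled_cov,
      canonical = canonical,
      groups = levels(grp),
      n_i = setNames(n_i, levels(grp)),
      N = N, g = g, p = p_sel,
      wilks_lambda = lambda_cur,
      p_in = p_in, p_out = p_out,
      individual = individual,
      feature_names = cols
    ),
    class = "stepwise_dfa"
  )
}

#' @export
print.stepwise_dfa <- function(x, ...) {
  cat(sprintf("Stepwise DFA: %d of %d features selected (N = %d calls, g = %d groups)\n",
              x$p, length(x$feature_names), x$N, x$g))
  if (x$empty) {
    cat("  <no feature met the entry criterion>\n")
  } else {
    cat(sprintf("  Wilks' lambda = %.4f; entry order: %s\n",
                x$wilks_lambda, paste(x$selected, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy the entry/removal trace of a stepwise DFA
#'
#' @param x A `stepwise_dfa` object.
#' @param ... Unused.
#' @return A tibble with one row per entry/removal step (feature, partial F,
#'   probability-of-F, Wilks' lambda after the step).
#' @export
tidy.stepwise_dfa <- function(x, ...) x$trace

#' One-row model summary of a stepwise DFA
#'
#' @param x A `stepwise_dfa` object.
#' @param ... Unused.
#' @return A tibble with `n_calls`, `n_groups`, `n_selected`,
#'   `wilks_lambda`, `chance_pct`.
#' @export
glance.stepwise_dfa <- function(x, ...) {
  tibble::tibble(
    n_calls = x$N, n_groups = x$g, n_selected = x$p,
    wilks_lambda = if (x$empty) NA_real_ else x$wilks_lambda,
    chance_pct = 100 / x$g
  )
}
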