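# Statistical stage: outcome rate summaries, Fisher's exact test with a
# Monte Carlo p-value variant, binomial and negative-binomial GLMs with
# likelihood-ratio term tests, VIF, Nagelkerke pseudo-R2, and backward
# elimination that always retains the treatment term.

#' Per-group desertion and ejection rates
#'
#' Desertion rate uses the full group size as denominator (all assigned
#' nests, including any lost to follow-up with `NA` response). Ejection
#' rate, defined only for the parasitized treatments, uses the nests with a
#' definitive eject/accept outcome as denominator: deserted nests and nests
#' without a known outcome are excluded.
#'
#' @param outcomes a data.frame with columns `treatment` and `response`
#'   (`eject`, `accept`, `desert`, or `NA` for no definitive outcome).
#' @return data.frame with one row per group: `treatment`, `n`, `n_desert`,
#'   `desertion_pct`, `n_outcome`, `n_eject`, `ejection_pct` (NA for the
#'   control group and for empty groups).
#' @export
proportion_summary <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("empty outcome table")
  groups <- c("control", "constant", "rearranged")
  groups <- groups[groups %in% unique(outcomes$treatment)]
  rows <- lapply(groups, function(g) {
    sub <- outcomes[outcomes$treatment == g, ]
    n <- nrow(sub)
    n_desert <- sum(sub$response == "desert", na.rm = TRUE)
    n_eject <- sum(sub$response == "eject", na.rm = TRUE)
    n_accept <- sum(sub$response == "accept", na.rm = TRUE)
    n_outcome <- n_eject + n_accept
    data.frame(
      treatment = g, n = n, n_desert = n_desert,
      desertion_pct = if (n > 0) 100 * n_desert / n else NA_real_,
      n_outcome = n_outcome, n_eject = n_eject,
      ejection_pct = if (g != "control" && n_outcome > 0)
        100 * n_eject / n_outcome else NA_real_)
  })
  do.call(rbind, rows)
}

#' Fisher's exact test for a 2x2 table, with a Monte Carlo variant
#'
#' The two-sided enumeration p-value sums the conditional (hypergeometric)
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table. The Monte Carlo p-value draws
#' `n_reps` tables with the same margins ([stats::r2dtable()]) and uses
#' `(1 + #{simulated tables at most as probable}) / (n_reps + 1)`. The
#' conditional maximum-likelihood odds ratio and its exact confidence
#' interval are those of [stats::fisher.test()].
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param n_reps number of Monte Carlo replicates (default 100,000).
#' @param seed optional integer seed for the Monte Carlo draw.
#' @param conf_level confidence level for the odds-ratio interval.
#' @return an object of class `fisher_mc`: list with `p_exact`, `p_mc`,
#'   `mc_se`, `odds_ratio`, `conf_int`, `n_reps`, `table`.
#' @export
fisher_exact <- function(tab, n_reps = 1e5, seed = NULL, conf_level = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be a 2x2 matrix")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a margin is zero")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  rel_tol <- 1 + 1e-7
  p_exact <- sum(probs[probs <= p_obs * rel_tol])

  if (!is.null(seed)) set.seed(seed)
  sims <- stats::r2dtable(n_reps, rowSums(tab), colSums(tab))
  x_sim <- vapply(sims, function(t) t[1, 1], numeric(1))
  p_sim <- stats::dhyper(x_sim, c1, N - c1, r1)
  hits <- sum(p_sim <= p_obs * rel_tol)
  p_mc <- (1 + hits) / (n_reps + 1)

  ft <- stats::fisher.test(tab, conf.level = conf_level)
  structure(
    list(p_exact = p_exact, p_mc = p_mc,
         mc_se = sqrt(p_exact * (1 - p_exact) / n_reps),
         odds_ratio = unname(ft$estimate), conf_int = as.numeric(ft$conf.int),
         n_reps = n_reps, table = tab),
    class = "fisher_mc")
}

#' @export
print.fisher_mc <- function(x, ...) {
  cat(sprintf(paste0("Fisher's exact test (2x2): p = %.4g ",
                     "(Monte Carlo p = %.4g, %d replicates)\n",
                     "conditional MLE odds ratio = %.3g, CI [%.3g, %.3g]\n"),
              x$p_exact, x$p_mc, x$n_reps,
              x$odds_ratio, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of
#' determination of predictor `j` regressed (with intercept) on the other
#' predictors.
#'
#' @param design numeric matrix of predictor columns (no intercept column),
#'   at least two columns, full column rank.
#' @return named numeric vector of VIFs, all >= 1.
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  if (ncol(design) < 2) stop("VIF needs at least 2 predictors")
  if (qr(cbind(1, design))$rank < ncol(design) + 1)
    stop("singular design: predictors are linearly dependent")
  out <- vapply(seq_len(ncol(design)), function(j) {
    fit <- stats::lm.fit(cbind(1, design[, -j, drop = FALSE]), design[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((design[, j] - mean(design[, j]))^2)
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(design)
  out
}

nagelkerke_r2 <- function(fit) {
  n <- stats::nobs(fit)
  ll_full <- as.numeric(stats::logLik(fit))
  null_fit <- suppressWarnings(
    stats::update(fit, . ~ 1, data = stats::model.frame(fit)))
  ll_null <- as.numeric(stats::logLik(null_fit))
  cox_snell <- 1 - exp(2 * (ll_null - ll_full) / n)
  cox_snell / (1 - exp(2 * ll_null / n))
}

# Shared result builder: term table with estimates, family-wise Wald CIs
# (Bonferroni over the estimated terms), single-term-deletion
# likelihood-ratio chi-square and p, and VIFs from the model matrix.
build_model_result <- function(fit, data, family_label, flags = character(0)) {
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  m <- length(cf)
  z <- stats::qnorm(1 - 0.05 / (2 * m))  # Bonferroni family-wise 95%
  terms_tab <- data.frame(term = names(cf), estimate = unname(cf),
                          ci_lo = unname(cf - z * se),
                          ci_hi = unname(cf + z * se),
                          chisq = NA_real_, p = NA_real_, vif = NA_real_)

  if (length(attr(stats::terms(fit), "term.labels")) >= 1) {
    # refits inside drop1 can re-raise convergence warnings already
    # captured (and flagged) on the primary fit
    d1 <- suppressWarnings(stats::drop1(fit, test = "LRT"))
    lab <- rownames(d1)[-1]
    lrt_col <- if ("LRT" %in% colnames(d1)) "LRT" else "Deviance"
    p_col <- grep("^Pr\\(", colnames(d1), value = TRUE)[1]
    asg <- attr(stats::model.matrix(fit), "assign")
    tl <- attr(stats::terms(fit), "term.labels")
    for (k in seq_along(lab)) {
      term_idx <- which(asg == match(lab[k], tl))
      terms_tab$chisq[term_idx] <- d1[[lrt_col]][k + 1]
      terms_tab$p[term_idx] <- d1[[p_col]][k + 1]
    }
  }

  mm <- stats::model.matrix(fit)
  pred <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  if (ncol(pred) >= 2) {
    v <- vif(pred)
    terms_tab$vif[match(names(v), terms_tab$term)] <- v
  }

  structure(
    list(terms = terms_tab, family = family_label,
         pseudo_r2 = nagelkerke_r2(fit), n = stats::nobs(fit),
         flags = flags, fit = fit),
    class = "model_result")
}

#' @export
print.model_result <- function(x, digits = 3, ...) {
  cat(sprintf("GLM (%s), n = %d, Nagelkerke R2 = %.2f\n",
              x$family, x$n, x$pseudo_r2))
  tt <- x$terms
  tt[-1] <- lapply(tt[-1], function(col) round(col, digits))
  print(tt, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

prepare_response_data <- function(outcomes) {
  sub <- outcomes[!is.na(outcomes$response) & outcomes$response != "desert" &
                    outcomes$treatment != "control", , drop = FALSE]
  if (nrow(sub) == 0) stop("no non-deserted parasitized nests to model")
  sub$ejected <- as.integer(sub$response == "eject")
  sub$treatment <- factor(sub$treatment, levels = c("constant", "rearranged"))
  if ("clutch_size" %in% names(sub))
    sub$clutch_size <- factor(sub$clutch_size)
  sub
}

#' Binomial GLM for the ejection response
#'
#' Fits `ejected ~ predictors` by maximum likelihood with a logit link on
#' the non-deserted parasitized nests (control nests have no foreign egg
#' to eject and are excluded). Term significance is the single-term
#' deletion likelihood-ratio chi-square; confidence intervals are
#' family-wise (Bonferroni-adjusted Wald); collinearity is reported as
#' VIF. Perfect or quasi-separation is flagged (`"separation"` in
#' `flags`) and a data-augmentation penalized refit -- pseudo-observations
#' at the predictor means acting as a weak prior -- is attached as the
#' `penalized` element; its estimates are finite where the ML ones are not.
#'
#' @param outcomes a nest-outcome data.frame (see [simulate_outcomes()]).
#' @param predictors character vector of predictor column names; must
#'   include `treatment`.
#' @return a `model_result` object.
#' @export
fit_response_model <- function(outcomes,
                               predictors = c("treatment", "nest_age",
                                              "laying_date", "clutch_size")) {
  sub <- prepare_response_data(outcomes)
  fml <- stats::reformulate(predictors, response = "ejected")
  flags <- character(0)
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = sub),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        flags <<- union(flags, "separation")
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    flags <- union(flags, "separation")
  res <- build_model_result(fit, sub, "binomial (logit link)", flags)
  if ("separation" %in% flags)
    res$penalized <- augmented_logit(fml, sub)
  res
}

# Documented fallback under separation: Clogg-style data augmentation --
# refit with 2p pseudo-observations at the predictor means, half successes,
# each with weight 1/2 (equivalent to a weak normal prior pulling
# estimates away from infinity).
augmented_logit <- function(fml, data) {
  mf <- stats::model.frame(fml, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(fml, data)
  p <- ncol(X)
  X_aug <- rbind(X, colMeans(X), colMeans(X))
  y_aug <- c(y, 0, 1)
  w <- c(rep(1, length(y)), rep(p / 2, 2))
  fit <- suppressWarnings(
    stats::glm.fit(X_aug, y_aug, weights = w, family = stats::binomial()))
  stats::setNames(fit$coefficients, colnames(X))
}

#' Negative-binomial GLM for the latency to ejection
#'
#' Fits `latency_days ~ predictors` on the ejecting nests with a log link
#' and maximum-likelihood dispersion ([MASS::glm.nb()]). When the
#' dispersion estimate diverges (data at or beyond the Poisson limit) or
#' the fit fails -- e.g. all latencies zero -- the model falls back to a
#' Poisson GLM and the result is flagged `"poisson_fallback"`.
#'
#' @inheritParams fit_response_model
#' @return a `model_result` object.
#' @export
fit_latency_model <- function(outcomes,
                              predictors = c("treatment", "nest_age",
                                             "laying_date", "clutch_size")) {
  sub <- outcomes[!is.na(outcomes$response) & outcomes$response == "eject", ,
                  drop = FALSE]
  if (nrow(sub) == 0) stop("no ejecting nests to model")
  if (any(is.na(sub$latency_days)) || any(sub$latency_days < 0) ||
      any(sub$latency_days != round(sub$latency_days)))
    stop("latency_days must be non-negative integers for all ejectors")
  sub$treatment <- factor(sub$treatment, levels = c("constant", "rearranged"))
  if ("clutch_size" %in% names(sub)) sub$clutch_size <- factor(sub$clutch_size)
  fml <- stats::reformulate(predictors, response = "latency_days")

  flags <- character(0)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = sub)),
    error = function(e) NULL)
  if (is.null(fit) || !is.null(fit$th.warn) || fit$theta > 1e4) {
    if (!is.null(fit) && fit$theta > 1e4)
      flags <- union(flags, "poisson_limit")
    flags <- union(flags, "poisson_fallback")
    fit <- stats::glm(fml, family = stats::poisson(), data = sub)
    res <- build_model_result(fit, sub, "poisson (log link; NB fallback)", flags)
  } else {
    res <- build_model_result(
      fit, sub, sprintf("negative binomial (log link, theta = %.3g)", fit$theta),
      flags)
    res$theta <- fit$theta
  }
  res
}

#' Backward elimination retaining the treatment term
#'
#' Starting from the full model, iteratively refits after deleting the
#' unprotected term with the largest single-term-deletion likelihood-ratio
#' p-value above `alpha`, until every unprotected term is significant. The
#' protected term (treatment, the predictor of main interest) is retained
#' regardless of its significance. Both the full and the final model are
#' returned.
#'
#' @param outcomes nest-outcome data.frame.
#' @param model `"response"` (binomial ejection model) or `"latency"`
#'   (negative-binomial latency model).
#' @param predictors starting predictor set; must contain `protected`.
#' @param alpha retention threshold for unprotected terms.
#' @param protected name of the always-kept predictor.
#' @return list with elements `full` and `final` (both `model_result`) and
#'   `dropped` (character vector, in elimination order).
#' @export
backward_eliminate <- function(outcomes, model = c("response", "latency"),
                               predictors = c("treatment", "nest_age",
                                              "laying_date", "clutch_size"),
                               alpha = 0.05, protected = "treatment") {
  model <- match.arg(model)
  if (!protected %in% predictors)
    stop("the protected term must be part of the starting predictors")
  fit_fun <- if (model == "response") fit_response_model else fit_latency_model

  term_p <- function(res, term) {
    # p of the whole term: rows of the coefficient table assigned to it
    tt <- res$terms
    idx <- grep(paste0("^", term), tt$term)
    p <- tt$p[idx]
    p <- p[!is.na(p)]
    if (!length(p)) NA_real_ else min(p)
  }

  current <- predictors
  full <- fit_fun(outcomes, predictors = current)
  res <- full
  dropped <- character(0)
  repeat {
    unprot <- setdiff(current, protected)
    if (!length(unprot)) break
    pvals <- vapply(unprot, function(tm) term_p(res, tm), numeric(1))
    if (all(is.na(pvals))) break
    worst <- unprot[which.max(pvals)]
    if (max(pvals, na.rm = TRUE) <= alpha) break
    current <- setdiff(current, worst)
    dropped <- c(dropped, worst)
    res <- fit_fun(outcomes, predictors = current)
  }
  list(full = full, final = res, dropped = dropped)
}
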