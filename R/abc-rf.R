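#' ABC random-forest model choice
#'
#' Trains a classification forest on the reference table (summaries ->
#' scenario label, with LDA axes appended as extra predictors), reads the
#' per-tree classification votes at the observed summary vector, selects the
#' scenario with most votes (ties: the lowest scenario index, logged in the
#' result), reports the out-of-bag misclassification fraction as the prior
#' error rate, and estimates the posterior probability of the selected
#' scenario with a second, regression forest trained on the out-of-bag
#' misclassification indicator and evaluated at the observed point
#' (posterior = 1 - predicted local error).
#'
#' @param rt a [generate_reference_table()] result with >= 2 scenarios
#' @param observed named summary vector with the reference-table schema
#' @param n_trees trees in each forest
#' @param add_lda append LDA axes ([fit_lda()]) to summaries (default TRUE)
#' @param seed optional RNG seed forwarded to the forests
#' @return object of class `model_choice_result`: `votes` (counts),
#'   `vote_fractions`, `selected`, `prior_error_rate`,
#'   `posterior_probability`, `n_trees`, `tie` flag
#' @export
model_choice <- function(rt, observed, n_trees = 1000, add_lda = TRUE,
                         seed = NULL) {
  if (nlevels(rt$scenario) < 2) stop("model choice needs >= 2 scenarios")
  if (!identical(colnames(rt$sumstats), names(observed)))
    stop("observed summary schema does not match the reference table")
  X <- rt$sumstats
  obs <- observed
  if (add_lda) {
    proj <- fit_lda(rt)
    X <- apply_lda(proj, X)
    obs <- apply_lda(proj, observed)
  }
  df <- as.data.frame(X)
  df$.scenario <- rt$scenario
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  fit <- ranger::ranger(dependent.variable.name = ".scenario", data = df,
                        num.trees = n_trees, seed = seed,
                        num.threads = 1, respect.unordered.factors = TRUE)
  newd <- as.data.frame(matrix(obs, 1, dimnames = list(NULL, names(obs))))
  pred <- predict(fit, data = newd, predict.all = TRUE, num.threads = 1)
  tree_votes <- factor(levels(rt$scenario)[pred$predictions[1, ]],
                       levels = levels(rt$scenario))
  votes <- table(tree_votes)
  sel <- which(votes == max(votes))
  tie <- length(sel) > 1
  selected <- levels(rt$scenario)[min(sel)]
  # regression forest on the OOB misclassification indicator
  oob <- fit$predictions
  mis <- as.numeric(oob != rt$scenario)
  df2 <- as.data.frame(X)
  df2$.miss <- mis
  fit2 <- ranger::ranger(dependent.variable.name = ".miss", data = df2,
                         num.trees = n_trees, seed = seed + 1L,
                         num.threads = 1)
  local_err <- predict(fit2, data = newd, num.threads = 1)$predictions
  structure(list(votes = votes,
                 vote_fractions = as.vector(votes) / sum(votes),
                 selected = selected, tie = tie,
                 prior_error_rate = fit$prediction.error,
                 posterior_probability = min(max(1 - local_err, 0), 1),
                 n_trees = n_trees, seed = seed),
            class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat("ABC-RF model choice\n")
  cat("  selected scenario:    ", x$selected, if (x$tie) " (tie)" else "", "\n", sep = "")
  fr <- setNames(sprintf("%.1f%%", 100 * x$vote_fractions), names(x$votes))
  cat("  votes:                ", paste(names(fr), fr, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  prior error rate:      %.3f\n", x$prior_error_rate))
  cat(sprintf("  posterior probability: %.3f\n", x$posterior_probability))
  invisible(x)
}

#' RF-regression posterior distributions of scenario parameters
#'
#' One regression forest per parameter, trained on the reference table of
#' the selected scenario. Posterior weights of the training draws are the
#' normalised leaf co-occurrence weights with the observed point (a training
#' draw gets weight where its in-bag copies share a terminal node with the
#' observed vector), and the posterior mean, median and quantiles are those
#' of the weighted empirical distribution. A parameter held constant by a
#' degenerate prior yields a zero-width posterior at that constant.
#'
#' @param rt a single-scenario reference table
#' @param observed named summary vector matching the table's schema
#' @param parameters parameter columns to estimate (default: all)
#' @param n_trees trees per forest
#' @param probs quantiles to report (default 0.025, 0.5, 0.975)
#' @param seed optional RNG seed
#' @param keep_weights return the per-draw weight matrix
#' @return object of class `parameter_posterior`: data.frame `estimates`
#'   with columns parameter, mean, median, q_lo, q_hi, oob_mse; optionally
#'   `weights`
#' @export
estimate_parameters <- function(rt, observed, parameters = NULL,
                                n_trees = 1000, probs = c(0.025, 0.5, 0.975),
                                seed = NULL, keep_weights = FALSE) {
  if (nlevels(droplevels(rt$scenario)) != 1)
    stop("parameter estimation expects a single-scenario reference table")
  if (!identical(colnames(rt$sumstats), names(observed)))
    stop("observed summary schema does not match the reference table")
  if (is.null(parameters)) parameters <- colnames(rt$params)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  X <- as.data.frame(rt$sumstats)
  newd <- as.data.frame(matrix(observed, 1,
                               dimnames = list(NULL, names(observed))))
  rows <- list(); wlist <- list()
  for (k in seq_along(parameters)) {
    pn <- parameters[k]
    y <- rt$params[[pn]]
    if (all(is.na(y))) next
    if (max(y) - min(y) < .Machine$double.eps * max(1, abs(max(y)))) {
      rows[[pn]] <- data.frame(parameter = pn, mean = y[1], median = y[1],
                               q_lo = y[1], q_hi = y[1], oob_mse = 0)
      next
    }
    df <- X
    df$.y <- y
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = n_trees, seed = seed + k,
                          num.threads = 1, keep.inbag = TRUE,
                          mtry = max(1, floor(ncol(X) / 3)))
    tn <- predict(fit, data = X, type = "terminalNodes",
                  num.threads = 1)$predictions
    to <- predict(fit, data = newd, type = "terminalNodes",
                  num.threads = 1)$predictions[1, ]
    inbag <- simplify2array(fit$inbag.counts)      # n x trees
    w <- numeric(nrow(X))
    for (b in seq_len(n_trees)) {
      m <- inbag[, b] * (tn[, b] == to[b])
      s <- sum(m)
      if (s > 0) w <- w + m / s
    }
    w <- w / sum(w)
    q <- .weighted_quantile(y, w, probs)
    rows[[pn]] <- data.frame(parameter = pn, mean = sum(w * y),
                             median = .weighted_quantile(y, w, 0.5),
                             q_lo = q[1], q_hi = q[length(q)],
                             oob_mse = fit$prediction.error)
    if (keep_weights) wlist[[pn]] <- w
  }
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  structure(list(estimates = est,
                 weights = if (keep_weights) wlist else NULL,
                 probs = probs, n_trees = n_trees, seed = seed),
            class = "parameter_posterior")
}

#' @export
print.parameter_posterior <- function(x, ...) {
  cat("ABC-RF parameter posteriors (weighted by leaf co-occurrence):\n")
  print.data.frame(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

# weighted empirical quantiles (type-1 inverse CDF on the weighted sample)
.weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Convert time estimates from generations to years
#'
#' years = generations x generation time. The per-year substitution rate is
#' reporting metadata only and never enters the coalescent simulation.
#'
#' @param value_generations value(s) in generations
#' @param generation_time_years generation time (years); must be positive
#' @return value(s) in years
#' @export
convert_units <- function(value_generations, generation_time_years = 6) {
  stopifnot(generation_time_years > 0)
  value_generations * generation_time_years
}
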