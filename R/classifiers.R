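# classifiers: Fellegi-Sunter naive Bayes, ECM, logistic, linear SVM -----

FS_EPS <- 1e-6

clamp01 <- function(x, eps = FS_EPS) pmin(pmax(x, eps), 1 - eps)

new_fs_model <- function(m, u, p, fields) {
  m <- clamp01(m)
  u <- clamp01(u)
  p <- clamp01(p)
  names(m) <- names(u) <- fields
  structure(list(m = m, u = u, p = p, fields = fields),
            class = c("fs_model", "linkage_model"))
}

#' Construct a Fellegi-Sunter model directly
#'
#' @param m Per-field probability of agreement given a true match.
#' @param u Per-field probability of agreement given a non-match.
#' @param p Prior match proportion.
#' @param fields Field names, in comparison-vector order.
#' @return An object of class `fs_model`.
#' @export
fs_model <- function(m, u, p, fields = names(m) %||% paste0("f", seq_along(m))) {
  if (length(m) != length(u)) {
    fl_stop("m and u must have the same length", class = "fl_config_error")
  }
  new_fs_model(m, u, p, fields)
}

#' @export
print.fs_model <- function(x, digits = 4, ...) {
  cat("Fellegi-Sunter linkage model\n")
  cat(sprintf("  prior match proportion p = %.*g\n", digits, x$p))
  tab <- rbind(m = x$m, u = x$u)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.fs_model <- function(object, ...) {
  c(setNames(object$m, paste0("m.", object$fields)),
    setNames(object$u, paste0("u.", object$fields)),
    p = object$p)
}

golden_matrix <- function(g) {
  stopifnot(inherits(g, "fl_golden"))
  list(scores = g$scores, y = g$labels == "match")
}

#' Fit the supervised naive Bayes (Fellegi-Sunter) classifier
#'
#' Estimates, for each matching variable, the probability that it agrees
#' given a true match (`m`) and given a non-match (`u`), plus the prior
#' match proportion, from a labeled golden dataset with Laplace smoothing:
#' `m_i = (sum of agreements over matches + s) / (n_match + 2 s)`.
#' Golden sets in this domain are tiny (a handful of verified matches), so
#' the default `s = 1` keeps estimates off the 0/1 boundary.
#'
#' @param g An `fl_golden` with both classes present.
#' @param smoothing Laplace smoothing constant `s > 0`.
#' @return An `fs_model`.
#' @export
fit_naive_bayes <- function(g, smoothing = 1) {
  gm <- golden_matrix(g)
  if (smoothing <= 0) fl_stop("smoothing must be > 0", class = "fl_config_error")
  if (!any(gm$y) || all(gm$y)) {
    fl_stop("golden dataset must contain both matches and non-matches",
            class = "fl_validation_error")
  }
  s <- smoothing
  n1 <- sum(gm$y)
  n0 <- sum(!gm$y)
  m <- (colSums(gm$scores[gm$y, , drop = FALSE], na.rm = TRUE) + s) / (n1 + 2 * s)
  u <- (colSums(gm$scores[!gm$y, , drop = FALSE], na.rm = TRUE) + s) / (n0 + 2 * s)
  new_fs_model(m, u, n1 / (n1 + n0), colnames(gm$scores))
}

#' Posterior match probability under a Fellegi-Sunter model
#'
#' Computes `P(match | gamma)` for binary agreement vectors assuming
#' conditional independence of fields:
#' `p * prod(m^g (1-m)^(1-g)) / (same + (1-p) * prod(u^g (1-u)^(1-g)))`.
#' The complementary non-match probability is `1 -` the returned value.
#' Fields whose score is `NA` (the `"ignore"` missing policy) contribute no
#' evidence.
#'
#' @param model An `fs_model`.
#' @param v A `comparison_matrix`, a pairs-by-fields 0/1 matrix, or a
#'   single vector.
#' @return Numeric vector of posterior match probabilities in `[0, 1]`.
#' @export
fs_posterior <- function(model, v) {
  stopifnot(inherits(model, "fs_model"))
  G <- if (inherits(v, "comparison_matrix")) v$scores
       else if (inherits(v, "fl_comparison")) matrix(v$scores, nrow = 1,
                                                     dimnames = list(NULL, names(v$scores)))
       else if (is.matrix(v)) v
       else matrix(v, nrow = 1)
  if (ncol(G) != length(model$m)) {
    fl_stop("comparison vector has %d fields, model has %d", ncol(G),
            length(model$m), class = "fl_config_error")
  }
  lm1 <- log(model$m); lm0 <- log1p(-model$m)
  lu1 <- log(model$u); lu0 <- log1p(-model$u)
  n <- nrow(G)
  la <- rep(log(model$p), n)
  lb <- rep(log1p(-model$p), n)
  for (k in seq_len(ncol(G))) {
    g <- G[, k]
    obs <- !is.na(g)
    la[obs] <- la[obs] + ifelse(g[obs] == 1L, lm1[k], lm0[k])
    lb[obs] <- lb[obs] + ifelse(g[obs] == 1L, lu1[k], lu0[k])
  }
  1 / (1 + exp(lb - la))
}

#' @export
predict.fs_model <- function(object, newdata, ...) {
  scores <- fs_posterior(object, newdata)
  link_scores(newdata, scores, classifier = "naive_bayes")
}

# ---- Expectation/Conditional Maximization (unsupervised) ----------------

ecm_loglik <- function(counts, G, m, u, p) {
  lj_m <- G %*% log(m) + (1 - G) %*% log1p(-m)
  lj_u <- G %*% log(u) + (1 - G) %*% log1p(-u)
  sum(counts * log(p * exp(lj_m) + (1 - p) * exp(lj_u)))
}

#' Fit the linkage mixture by expectation/conditional maximization
#'
#' Unsupervised estimation of the Fellegi-Sunter parameters from the
#' comparison vectors alone, treating match status as the latent class of a
#' two-component mixture of independent Bernoulli fields. The E-step
#' computes per-pair match posteriors under the current parameters; the
#' M-step updates `p`, `m` and `u` from the posterior weights. Iteration
#' stops when the observed-data log-likelihood changes by less than `tol`.
#' Component labels are resolved by requiring `m >= u` on a majority of
#' fields (components are swapped otherwise). Like any EM method this can
#' land on a local maximum; `restarts` adds seeded random initializations
#' and keeps the best log-likelihood.
#'
#' @param vectors A `comparison_matrix` or 0/1 score matrix.
#' @param init Initial `fs_model`; defaults to m = 0.9, u = 0.1, p = 0.05
#'   per field.
#' @param tol Convergence tolerance on the log-likelihood, default `1e-6`.
#' @param max_iter Maximum iterations, default 200.
#' @param restarts Number of additional random initializations.
#' @param seed Seed for the random restarts.
#' @return An object of class `fl_ecm_fit`: list with the fitted `model`,
#'   the log-likelihood `trace`, `iterations` and a `converged` flag.
#' @export
fit_ecm <- function(vectors, init = NULL, tol = 1e-6, max_iter = 200L,
                    restarts = 0L, seed = 1L) {
  G_full <- if (inherits(vectors, "comparison_matrix")) vectors$scores else vectors
  stopifnot(is.matrix(G_full))
  if (anyNA(G_full)) {
    fl_stop("ECM requires complete comparison vectors (use missing_policy = 'disagree')",
            class = "fl_config_error")
  }
  k <- ncol(G_full)
  fields <- colnames(G_full) %||% paste0("f", seq_len(k))
  # collapse to unique agreement patterns: EM cost becomes O(2^k) per step
  key <- as.vector(G_full %*% (2^(seq_len(k) - 1)))
  tab <- table(key)
  patterns <- as.numeric(names(tab))
  counts <- as.numeric(tab)
  G <- t(vapply(patterns, function(x) as.numeric(bitwAnd(x, 2^(seq_len(k) - 1)) > 0),
                numeric(k)))
  if (k == 1) G <- matrix(G, ncol = 1)
  colnames(G) <- fields
  if (nrow(G) < 2) {
    fl_stop("degenerate input: all comparison vectors are identical, the mixture is unidentifiable",
            class = "fl_convergence_error",
            data = list(trace = ecm_loglik(counts, G, rep(0.5, k), rep(0.5, k), 0.5)))
  }

  run_once <- function(m, u, p) {
    trace <- numeric(0)
    converged <- FALSE
    iterations <- 0L
    for (it in seq_len(max_iter)) {
      ll <- ecm_loglik(counts, G, m, u, p)
      trace <- c(trace, ll)
      if (it > 1 && abs(ll - trace[it - 1]) < tol) {
        converged <- TRUE
        iterations <- it - 1L
        break
      }
      iterations <- it
      # E-step
      lj_m <- as.vector(G %*% log(m) + (1 - G) %*% log1p(-m)) + log(p)
      lj_u <- as.vector(G %*% log(u) + (1 - G) %*% log1p(-u)) + log1p(-p)
      w <- 1 / (1 + exp(lj_u - lj_m))
      # M-step (conditional maximizations)
      cw <- counts * w
      cv <- counts * (1 - w)
      p <- clamp01(sum(cw) / sum(counts))
      m <- clamp01(as.vector(t(G) %*% cw) / sum(cw))
      u <- clamp01(as.vector(t(G) %*% cv) / sum(cv))
    }
    list(m = m, u = u, p = p, trace = trace, converged = converged,
         iterations = iterations, ll = trace[length(trace)])
  }

  init <- init %||% fs_model(rep(0.9, k), rep(0.1, k), 0.05, fields)
  stopifnot(inherits(init, "fs_model"))
  best <- run_once(init$m, init$u, init$p)
  if (restarts > 0) {
    starts <- with_seed(derive_seed(seed, "ecm-restarts"), {
      lapply(seq_len(restarts), function(i) {
        list(m = runif(k, 0.5, 0.99), u = runif(k, 0.01, 0.5), p = runif(1, 0.001, 0.2))
      })
    })
    for (st in starts) {
      cand <- run_once(st$m, st$u, st$p)
      if (cand$ll > best$ll) best <- cand
    }
  }
  m <- best$m; u <- best$u; p <- best$p
  if (mean(m >= u) < 0.5) {  # label switching: match class must agree more
    tmp <- m; m <- u; u <- tmp
    p <- 1 - p
  }
  structure(
    list(model = new_fs_model(m, u, p, fields), trace = best$trace,
         iterations = best$iterations, converged = best$converged),
    class = "fl_ecm_fit"
  )
}

#' @export
print.fl_ecm_fit <- function(x, ...) {
  cat(sprintf("ECM fit: %d iteration(s), %sconverged, log-likelihood %.4f\n",
              x$iterations, if (x$converged) "" else "NOT ",
              x$trace[length(x$trace)]))
  print(x$model)
  invisible(x)
}

#' @export
predict.fl_ecm_fit <- function(object, newdata, ...) {
  scores <- fs_posterior(object$model, newdata)
  link_scores(newdata, scores, classifier = "ecm")
}

# ---- weight models: logistic regression and linear SVM ------------------

new_weight_model <- function(weights, intercept, kind, fields) {
  if (!all(is.finite(c(weights, intercept)))) {
    fl_stop("non-finite coefficients in %s fit", kind, class = "fl_convergence_error")
  }
  structure(list(weights = setNames(weights, fields), intercept = intercept,
                 kind = kind, fields = fields),
            class = c("weight_model", "linkage_model"))
}

#' @export
print.weight_model <- function(x, digits = 4, ...) {
  cat(sprintf("%s linkage model\n",
              switch(x$kind, logistic = "Logistic-regression", svm = "Linear-SVM")))
  print(round(c(intercept = x$intercept, x$weights), digits))
  invisible(x)
}

#' @export
coef.weight_model <- function(object, ...) {
  c(intercept = object$intercept, object$weights)
}

#' Fit ridge-penalized logistic regression on a golden dataset
#'
#' Maximizes the binomial log-likelihood minus `ridge/2 * ||w||^2` (the
#' intercept is not penalized) by Newton / iteratively reweighted least
#' squares. Golden datasets here are usually linearly separable, so a
#' positive ridge is required for the optimum to exist; predictions are
#' sigmoid-mapped probabilities.
#'
#' @param g An `fl_golden` with both classes present.
#' @param ridge L2 penalty, default `1e-4`.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the gradient norm.
#' @return A `weight_model` of kind `"logistic"`.
#' @export
fit_logistic <- function(g, ridge = 1e-4, max_iter = 100L, tol = 1e-8) {
  gm <- golden_matrix(g)
  if (!any(gm$y) || all(gm$y)) {
    fl_stop("golden dataset must contain both matches and non-matches",
            class = "fl_validation_error")
  }
  if (ridge <= 0) fl_stop("ridge must be > 0", class = "fl_config_error")
  X <- cbind(1, gm$scores)
  y <- as.numeric(gm$y)
  k <- ncol(X)
  beta <- numeric(k)
  pen <- diag(c(0, rep(ridge, k - 1)), k)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    grad <- as.vector(t(X) %*% (y - mu)) - pen %*% beta
    if (sqrt(sum(grad^2)) < tol) {
      return(new_weight_model(beta[-1], beta[1], "logistic", colnames(gm$scores)))
    }
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- t(X * W) %*% X + pen
    beta <- beta + solve(H, grad)
  }
  fl_stop("logistic regression did not converge in %d iterations (gradient norm %.3g)",
          max_iter, sqrt(sum(grad^2)), class = "fl_convergence_error")
}

#' Fit a linear support vector machine on a golden dataset
#'
#' Minimizes the L2-regularized hinge loss by deterministic (seeded)
#' stochastic subgradient descent in the Pegasos style. The classifier is
#' linear and non-probabilistic: predictions are 0/1 and the decision
#' threshold cannot be moved from 0.5.
#'
#' @param g An `fl_golden` with both classes present.
#' @param regularization L2 penalty `lambda`, default 0.01.
#' @param epochs Passes over the data.
#' @param seed Shuffling seed; the fit is identical for identical seeds.
#' @return A `weight_model` of kind `"svm"`.
#' @export
fit_svm <- function(g, regularization = 0.01, epochs = 200L, seed = 1L) {
  gm <- golden_matrix(g)
  if (!any(gm$y) || all(gm$y)) {
    fl_stop("golden dataset must contain both matches and non-matches",
            class = "fl_validation_error")
  }
  X <- gm$scores
  y <- ifelse(gm$y, 1, -1)
  n <- nrow(X)
  k <- ncol(X)
  lambda <- regularization
  w <- numeric(k)
  b <- 0
  with_seed(derive_seed(seed, "svm-shuffle"), {
    t <- 0L
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1L
        eta <- 1 / (lambda * t)
        margin <- y[i] * (sum(w * X[i, ]) + b)
        w <- (1 - eta * lambda) * w
        if (margin < 1) {
          w <- w + eta * y[i] * X[i, ]
          b <- b + eta * y[i]
        }
      }
    }
  })
  new_weight_model(w, b, "svm", colnames(X))
}

#' @export
predict.weight_model <- function(object, newdata, ...) {
  G <- if (inherits(newdata, "comparison_matrix")) newdata$scores else newdata
  if (anyNA(G)) {
    fl_stop("weight models require complete comparison vectors (missing_policy = 'disagree')",
            class = "fl_config_error")
  }
  eta <- as.vector(G %*% object$weights) + object$intercept
  scores <- if (object$kind == "logistic") plogis(eta) else as.numeric(eta > 0)
  link_scores(newdata, scores,
              classifier = if (object$kind == "logistic") "logistic_regression" else "svm")
}

# ---- link scores and threshold classification ---------------------------

link_scores <- function(newdata, scores, classifier) {
  pairs <- if (inherits(newdata, "comparison_matrix")) cm_pairs(newdata) else {
    data.frame(dataset_a = NA_character_,
               record_id_a = sprintf("a%d", seq_along(scores)),
               dataset_b = NA_character_,
               record_id_b = sprintf("b%d", seq_along(scores)),
               stringsAsFactors = FALSE)
  }
  pairs$score <- scores
  structure(pairs, class = c("fl_link_scores", "data.frame"),
            classifier = classifier)
}

#' Designate links by thresholding match scores
#'
#' A pair is a link iff its score is *strictly* greater than the threshold.
#' SVM scores are binary, so their threshold is fixed at 0.5; any other
#' value is a configuration error.
#'
#' @param scores An `fl_link_scores` object (from a classifier `predict`
#'   method).
#' @param threshold Number in `[0, 1]`.
#' @return The linked subset, class `fl_link_set`, with the classifier and
#'   threshold attached as attributes.
#' @export
classify_links <- function(scores, threshold) {
  stopifnot(inherits(scores, "fl_link_scores"))
  if (threshold < 0 || threshold > 1) {
    fl_stop("threshold must lie in [0, 1]", class = "fl_config_error")
  }
  classifier <- attr(scores, "classifier")
  if (identical(classifier, "svm") && threshold != 0.5) {
    fl_stop("the SVM is a binary classifier: its threshold cannot be changed from 0.5",
            class = "fl_config_error")
  }
  links <- scores[scores$score > threshold, , drop = FALSE]
  rownames(links) <- NULL
  structure(as.data.frame(links), class = c("fl_link_set", "data.frame"),
            classifier = classifier, threshold = threshold)
}

#' Serialize a linkage model to JSON
#'
#' Writes the model parameters (m/u/p for probabilistic models, weights and
#' intercept for weight models) with the field order, so fits can be reused
#' across sessions.
#'
#' @param model An `fs_model` or `weight_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    fl_stop("jsonlite is required for model serialization", class = "fl_config_error")
  }
  obj <- if (inherits(model, "fs_model")) {
    list(type = "fellegi_sunter", fields = model$fields,
         m = unname(model$m), u = unname(model$u), p = model$p)
  } else if (inherits(model, "weight_model")) {
    list(type = model$kind, fields = model$fields,
         weights = unname(model$weights), intercept = model$intercept)
  } else {
    fl_stop("unsupported model class", class = "fl_config_error")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
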