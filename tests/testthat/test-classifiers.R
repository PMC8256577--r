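test_that("naive Bayes estimates m/u/p with Laplace smoothing", {
  # hand arithmetic: two matches with agreement 1 and 0, s = 1
  g <- golden_from_scores(matrix(c(1, 0, 1, 0), ncol = 1),
                          c("match", "match", "nonmatch", "nonmatch"))
  fit <- fit_naive_bayes(g, smoothing = 1)
  expect_equal(unname(fit$m), (1 + 1) / (2 + 2))
  expect_equal(unname(fit$u), (1 + 1) / (2 + 2))
  expect_equal(fit$p, 0.5)

  # separable limit: s -> 0 drives m -> 1, u -> 0, clamped inside (0, 1)
  g2 <- golden_from_scores(matrix(c(1, 1, 0, 0, 0), ncol = 1),
                           c("match", "match", rep("nonmatch", 3)))
  fit2 <- fit_naive_bayes(g2, smoothing = 1e-12)
  expect_lt(fit2$m, 1)
  expect_gt(fit2$m, 1 - 1e-5)
  expect_lt(fit2$u, 1e-5)
  expect_equal(fit2$p, 2 / 5)

  g3 <- golden_from_scores(matrix(c(1, 1), ncol = 1), c("match", "match"))
  expect_error(fit_naive_bayes(g3), class = "fl_validation_error")
  expect_error(fit_naive_bayes(g, smoothing = 0), class = "fl_config_error")
})

test_that("fs_posterior matches direct Bayes arithmetic and enumeration", {
  model <- fs_model(m = c(0.9, 0.9), u = c(0.1, 0.1), p = 0.5)
  expect_equal(round(fs_posterior(model, c(1, 1)), 4), 0.9878)

  # uninformative fields: m = u gives the prior for every pattern
  flat <- fs_model(m = c(0.4, 0.4), u = c(0.4, 0.4), p = 0.3)
  for (g1 in 0:1) for (g2 in 0:1) {
    expect_equal(fs_posterior(flat, c(g1, g2)), 0.3, tolerance = 1e-12)
  }

  # exhaustive-enumeration oracle over all 2^k patterns, k <= 4
  set.seed(8)
  for (k in 2:4) {
    m <- runif(k, 0.6, 0.99)
    u <- runif(k, 0.01, 0.4)
    p <- runif(1, 0.01, 0.5)
    model_k <- fs_model(m, u, p)
    patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
    colnames(patterns) <- model_k$fields
    got <- fs_posterior(model_k, patterns)
    for (r in seq_len(nrow(patterns))) {
      gam <- patterns[r, ]
      num <- p * prod(m^gam * (1 - m)^(1 - gam))
      den <- num + (1 - p) * prod(u^gam * (1 - u)^(1 - gam))
      expect_equal(got[r], num / den, tolerance = 1e-12)
    }
    # match and non-match posteriors always sum to one
    nonmatch <- 1 - got
    expect_true(all(abs(got + nonmatch - 1) < 1e-15))
  }
})

test_that("naive Bayes separates verified matches on a study pair", {
  st <- default_nb_study()
  u <- st$universe
  spec <- default_matching_specs()[["VC-NFI"]]
  cand <- propose_candidates(u$datasets$VC, u$datasets$NFI, spec)
  matches <- verify_candidates(cand, u$truth)
  scr <- scramble_nonmatches(u$datasets$VC, u$datasets$NFI, 100, spec, seed = 2)
  g <- assemble_golden(matches, scr, u$datasets$VC, u$datasets$NFI, spec)
  fit <- fit_naive_bayes(g)
  post <- fs_posterior(fit, g$scores)
  expect_true(all(post[g$labels == "match"] > 0.5))
  expect_true(all(post[g$labels == "match"] > post[g$labels == "nonmatch"]))
})

test_that("ECM recovers known mixture parameters and is monotone", {
  m_true <- c(0.95, 0.9, 0.9)
  u_true <- c(0.05, 0.02, 0.1)
  p_true <- 0.05
  n <- 30000
  set.seed(14)
  z <- runif(n) < p_true
  G <- sapply(1:3, function(k) {
    as.integer(runif(n) < ifelse(z, m_true[k], u_true[k]))
  })
  colnames(G) <- c("incident_date", "vessel_official_number", "latlon")
  fit <- fit_ecm(G)
  expect_true(fit$converged)
  expect_true(all(abs(fit$model$m - m_true) < 0.03))
  expect_true(all(abs(fit$model$u - u_true) < 0.03))
  expect_lt(abs(fit$model$p - p_true), 0.03)
  # observed-data log-likelihood never decreases
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("ECM stops immediately at a fixed point and flags degeneracy", {
  set.seed(15)
  G <- matrix(as.integer(runif(600) < 0.3), ncol = 2,
              dimnames = list(NULL, c("incident_date", "incident_state")))
  fit <- fit_ecm(G)
  # re-initializing at the converged parameters takes a single iteration
  refit <- fit_ecm(G, init = fit$model)
  expect_equal(refit$iterations, 1L)
  expect_equal(refit$model$m, fit$model$m, tolerance = 1e-3)
  # ... and leaves the posteriors (E-step weights) essentially unchanged
  expect_equal(fs_posterior(refit$model, G), fs_posterior(fit$model, G),
               tolerance = 1e-3)

  G_flat <- matrix(1L, nrow = 50, ncol = 2,
                   dimnames = list(NULL, c("incident_date", "incident_state")))
  expect_error(fit_ecm(G_flat), class = "fl_convergence_error")
})

test_that("logistic regression matches a reference fit and its limits", {
  # perfectly separable one-field golden set
  g <- golden_from_scores(matrix(c(rep(1, 5), rep(0, 40)), ncol = 1),
                          c(rep("match", 5), rep("nonmatch", 40)))
  fit <- fit_logistic(g, ridge = 1e-4)
  expect_gt(plogis(fit$intercept + fit$weights[[1]]), 0.99)
  expect_lt(plogis(fit$intercept), 0.01)

  # reference oracle: stats::glm on a non-separable two-field set
  set.seed(16)
  X <- matrix(rbinom(400, 1, 0.4), ncol = 2)
  y <- rbinom(200, 1, plogis(-1 + 1.5 * X[, 1] - 0.5 * X[, 2]))
  g2 <- golden_from_scores(X, ifelse(y == 1, "match", "nonmatch"))
  fit2 <- fit_logistic(g2, ridge = 1e-8)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(c(fit2$intercept, fit2$weights)), unname(coef(ref)),
               tolerance = 1e-4)

  # null signal: labels independent of the fields
  g3 <- golden_from_scores(matrix(rep(c(0, 1), 50), ncol = 1),
                           rep(c("match", "nonmatch", "nonmatch", "match"), 25))
  fit3 <- fit_logistic(g3, ridge = 1e-4)
  expect_lt(abs(fit3$weights[[1]]), 0.05)
  expect_equal(plogis(fit3$intercept), 0.5, tolerance = 0.02)

  # duplicating every row leaves the (scale-invariant) MLE unchanged
  g4 <- golden_from_scores(rbind(X, X), c(g2$labels, g2$labels))
  fit4 <- fit_logistic(g4, ridge = 1e-8)
  expect_equal(fit4$weights, fit2$weights, tolerance = 1e-3)
})

test_that("the linear SVM separates, is deterministic, and matches e1071", {
  g <- golden_from_scores(
    rbind(matrix(1, 6, 2), matrix(c(0, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE),
          matrix(0, 20, 2)),
    c(rep("match", 6), rep("nonmatch", 23)))
  fit <- fit_svm(g, seed = 5)
  pred <- predict(fit, g$scores)
  expect_equal(pred$score, as.numeric(g$labels == "match"))  # training error 0

  # reference oracle: e1071's linear SVM predicts the same labels
  ref <- e1071::svm(x = g$scores, y = factor(g$labels), kernel = "linear",
                    scale = FALSE)
  expect_equal(as.character(predict(ref, g$scores)),
               ifelse(pred$score == 1, "match", "nonmatch"))

  # same seed, same weights; different seed may differ
  expect_identical(coef(fit_svm(g, seed = 5)), coef(fit))

  # inseparable degenerate input: identical vectors, mixed labels
  g_deg <- golden_from_scores(matrix(1, 10, 2),
                              c(rep("match", 3), rep("nonmatch", 7)))
  fit_deg <- fit_svm(g_deg, seed = 1)
  expect_true(all(predict(fit_deg, g_deg$scores)$score == 0))  # majority class
})

test_that("classify_links applies a strict threshold with SVM guard", {
  scores <- structure(
    data.frame(dataset_a = "CFID", record_id_a = c("a1", "a2", "a3"),
               dataset_b = "VC", record_id_b = c("b1", "b2", "b3"),
               score = c(0.006, 0.005, 0.9), stringsAsFactors = FALSE),
    class = c("fl_link_scores", "data.frame"), classifier = "naive_bayes")
  links <- classify_links(scores, 0.005)
  expect_equal(links$record_id_a, c("a1", "a3"))  # 0.005 itself is a non-link
  expect_equal(nrow(classify_links(scores, 0)), 3)

  # lowering the threshold never removes a link
  thresholds <- sort(runif(10))
  prev <- NULL
  for (thr in rev(thresholds)) {
    cur <- classify_links(scores, thr)$record_id_a
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }

  svm_scores <- scores
  attr(svm_scores, "classifier") <- "svm"
  svm_scores$score <- c(0, 1, 1)
  expect_error(classify_links(svm_scores, 0.2), class = "fl_config_error")
  expect_equal(nrow(classify_links(svm_scores, 0.5)), 2)
  expect_error(classify_links(scores, 1.5), class = "fl_config_error")
})

test_that("model serialization round-trips through JSON", {
  model <- fs_model(m = c(0.9, 0.8), u = c(0.1, 0.05), p = 0.02,
                    fields = c("incident_date", "incident_state"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$type, "fellegi_sunter")
  expect_equal(obj$m, unname(model$m))
  expect_equal(obj$fields, model$fields)
})
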