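test_that("kernel identities hold: K(x,x)=1, symmetry, closed forms", {
  kp <- kernel_params(1)
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(2); z <- rnorm(2)
    expect_equal(rbf_kernel(x, x, kp), 1)
    expect_equal(rbf_kernel(x, z, kp), rbf_kernel(z, x, kp))
    expect_gt(rbf_kernel(x, z, kp), 0)
    expect_lte(rbf_kernel(x, z, kp), 1)
  }
  # ||x - xi||^2 = 1, gamma = 1 -> exp(-1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), kp), exp(-1))
  # grid value gamma = 2^-3 with squared distance 8 -> exp(-1)
  expect_equal(rbf_kernel(c(0, 0), c(2, 2), kernel_params(2^-3)), exp(-1))
  # sigma is an explicit divisor of gamma
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), kernel_params(2, sigma = 2)),
               exp(-1))
  expect_error(rbf_kernel(c(NA, 0), c(0, 0), kp), "finite")
  expect_error(kernel_params(0), "gamma")
  expect_error(kernel_params(1, sigma = -1), "sigma")
})

test_that("two separable points: equal |dual coefficients| matching the brute-force dual", {
  tab <- data.frame(f1 = c(0, 1), f2 = c(0, 1), label = c(-1, 1))
  fit <- breath_svm(tab, gamma = 1, C = 10, tol = 1e-8,
                    scaling = identity_scaling())
  expect_equal(fit$n_sv, 2)
  expect_equal(fit$alpha[1], fit$alpha[2], tolerance = 1e-6)
  expect_equal(classify(fit, matrix(c(0, 0), 1)), "low")
  expect_equal(classify(fit, matrix(c(1, 1), 1)), "high")

  # brute force: with a1 = a2 = a, maximize 2a - a^2 (1 - K12) over a grid
  K12 <- exp(-2)
  agrid <- seq(0, 10, by = 1e-4)
  obj <- 2 * agrid - agrid^2 * (1 - K12)
  a_star <- agrid[which.max(obj)]
  expect_equal(fit$alpha[1], a_star, tolerance = 1e-3)
})

test_that("RBF SVM separates the XOR configuration", {
  tab <- data.frame(f1 = c(0, 1, 0, 1), f2 = c(0, 1, 1, 0),
                    label = c(1, 1, -1, -1))
  fit <- breath_svm(tab, gamma = 1, C = 1, tol = 1e-6,
                    scaling = identity_scaling())
  pred <- classify(fit, as.matrix(tab[, c("f1", "f2")]))
  expect_equal(pred, ifelse(tab$label > 0, "high", "low"))
})

test_that("duplicated point with conflicting labels pins both dual coefficients at C", {
  tab <- data.frame(f1 = c(0.5, 0.5), f2 = c(0.5, 0.5), label = c(1, -1))
  fit <- breath_svm(tab, gamma = 1, C = 1, tol = 1e-6,
                    scaling = identity_scaling())
  expect_equal(fit$n_sv, 2)
  expect_equal(unname(fit$alpha), c(1, 1), tolerance = 1e-9)
})

test_that("dual feasibility holds after training on random problems", {
  for (s in 1:20) {
    p <- random_problem(s)
    C <- sample(c(0.5, 1, 4), 1)
    fit <- breath_svm(p$table, gamma = 0.5, C = C, seed = s,
                      scaling = identity_scaling())
    expect_true(all(fit$alpha >= 0 & fit$alpha <= C + 1e-12))
    expect_lte(abs(sum(fit$dual_coefs)), fit$tol)
  }
})

test_that("SMO objective and predictions match the QP oracle on small problems", {
  skip_if_not_installed("kernlab")
  worst <- 0; disagreements <- 0; n_checked <- 0
  for (s in 1:50) {
    p <- random_problem(s)
    n <- nrow(p$X)
    set.seed(1000 + s)
    gamma <- sample(c(0.25, 0.5, 1, 2), 1)
    C <- sample(c(0.5, 1, 4), 1)
    fit <- breath_svm(p$table, gamma = gamma, C = C, tol = 1e-8,
                      max_passes = 2000, seed = s,
                      scaling = identity_scaling())
    K <- exp(-gamma * as.matrix(dist(p$X))^2)
    a_or <- qp_oracle(K, p$y, C)
    a_smo <- numeric(n)
    svidx <- apply(fit$support_vectors, 1,
                   function(v) which.min(colSums((t(p$X) - v)^2)))
    a_smo[svidx] <- fit$alpha
    worst <- max(worst, abs(dual_obj(K, p$y, a_smo) - dual_obj(K, p$y, a_or)))

    # decision-value agreement on random probes, away from the boundary
    P <- matrix(rnorm(40), 20, 2)
    f_smo <- decision_value(fit, P)
    Kp <- exp(-gamma * (outer(rowSums(P^2), rowSums(p$X^2), "+") -
                          2 * P %*% t(p$X)))
    fnob <- drop(Kp %*% (a_or * p$y))
    free <- which(a_or > 1e-6 & a_or < C - 1e-6)
    b_or <- if (length(free)) mean(p$y[free] - (K %*% (a_or * p$y))[free])
            else fit$bias
    f_or <- fnob + b_or
    m <- abs(f_or) > 1e-2
    n_checked <- n_checked + sum(m)
    disagreements <- disagreements + sum(sign(f_smo[m]) != sign(f_or[m]))
  }
  expect_lt(worst, 1e-4)
  expect_equal(disagreements, 0)
  expect_gt(n_checked, 500)
})

test_that("decision_value matches an independent summation and handles edge models", {
  # empty model returns the bias everywhere
  empty <- manual_model(matrix(numeric(0), 0, 2), numeric(0), bias = 0.7)
  expect_equal(decision_value(empty, c(0.3, 0.4)), 0.7)
  # one support vector at the probe, unit coefficient, zero bias -> 1
  one <- manual_model(c(0.2, 0.8), coefs = 1)
  expect_equal(decision_value(one, c(0.2, 0.8)), 1)
  expect_error(decision_value(one, c(1, 2, 3)), "features")

  p <- random_problem(77, n = 15)
  fit <- breath_svm(p$table, gamma = 0.7, C = 2, seed = 1,
                    scaling = identity_scaling())
  set.seed(42)
  probes <- matrix(rnorm(200), 100, 2)
  f <- decision_value(fit, probes)
  # independent elementwise summation
  f_ref <- apply(probes, 1, function(x) {
    s <- fit$bias
    for (i in seq_len(fit$n_sv))
      s <- s + fit$dual_coefs[i] *
        exp(-0.7 * sum((x - fit$support_vectors[i, ])^2))
    s
  })
  expect_equal(f, f_ref, tolerance = 1e-10)

  # invariance under permutation of the support vectors
  perm <- sample(fit$n_sv)
  fit2 <- fit
  fit2$support_vectors <- fit$support_vectors[perm, , drop = FALSE]
  fit2$dual_coefs <- fit$dual_coefs[perm]
  expect_equal(decision_value(fit2, probes), f, tolerance = 1e-12)
})

test_that("classify applies stored scaling, breaks ties toward high, rejects bad input", {
  # model with bias exactly 0 and no SVs: decision value 0 -> high
  tie <- manual_model(matrix(numeric(0), 0, 2), numeric(0), bias = 0)
  expect_equal(classify(tie, c(0.1, 0.2)), "high")
  expect_equal(classify(manual_model(matrix(numeric(0), 0, 2), numeric(0),
                                     bias = -0.1), c(0.1, 0.2)), "low")
  expect_error(classify(tie, c(NA, 1)), "finite")

  # scaling is applied to raw inputs: train on raw features, classify raw
  runs <- generate_dataset(3, short_protocol(), short_sensors(0.02),
                           master_seed = 31)
  scheme <- segment_scheme(list(Steady = c(70, 110)))
  tab <- build_design(runs, scheme, "Steady", period = 5)
  fit <- breath_svm(tab, gamma = 0.5, C = 1)
  pred <- classify(fit, as.matrix(tab[, c("f1", "f2")]))
  expect_equal(pred, ifelse(tab$label > 0, "high", "low"))
})

test_that("training is deterministic for a fixed seed and validates input", {
  p <- random_problem(5, n = 12)
  f1 <- breath_svm(p$table, gamma = 1, C = 1, seed = 9)
  f2 <- breath_svm(p$table, gamma = 1, C = 1, seed = 9)
  expect_identical(f1$dual_coefs, f2$dual_coefs)
  expect_identical(f1$bias, f2$bias)

  single <- data.frame(f1 = 1:3, f2 = 1:3, label = 1)
  expect_error(breath_svm(single, gamma = 1, C = 1), "both classes")
  expect_error(breath_svm(p$table[0, ], gamma = 1, C = 1), "empty")
  expect_error(breath_svm(p$table, gamma = 1, C = -1), "C must be")
  bad <- p$table; bad$label[1] <- 2
  expect_error(breath_svm(bad, gamma = 1, C = 1), "encoded")
})
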