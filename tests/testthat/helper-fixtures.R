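# Shared fixtures. Everything is generated in code; nothing is stored.

quiet_sensors <- function() default_sensors(noise_sd = 0)

# short protocol for fast simulator tests: same phase structure, 1/5 scale
short_protocol <- function() {
  flow_protocol(data.frame(
    name  = c("clean", "introduce", "transport", "steady", "clear"),
    start = c(0, 60, 90, 120, 180),
    end   = c(60, 90, 120, 180, 240),
    flow  = c(1.5, 0, 0.5, 0, 1.5)
  ))
}

short_sensors <- function(noise_sd = 0) {
  lapply(default_sensors(noise_sd), function(s) { s$lag <- 10; s })
}

# hand-built model: support vectors / coefficients chosen directly,
# identity scaling so raw space == scaled space
manual_model <- function(sv, coefs, bias = 0, gamma = 1,
                         scaling = rbind(min = c(0, 0), max = c(1, 1))) {
  sv <- if (is.matrix(sv)) sv else matrix(sv, ncol = 2, byrow = TRUE)
  structure(
    list(support_vectors = sv, dual_coefs = coefs, alpha = abs(coefs),
         sv_labels = ifelse(coefs >= 0, 1, -1), bias = bias,
         n_sv = nrow(sv), kernel = kernel_params(gamma),
         C = 1, tol = 1e-3, seed = 1L, passes = 0L,
         scaling = scaling, label_map = c(`1` = "high", `-1` = "low"),
         call = NULL),
    class = "breath_svm"
  )
}

identity_scaling <- function(d = 2) {
  rbind(min = rep(0, d), max = rep(1, d))
}

# small random binary problem in the unit square
random_problem <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(6:20, 1)
  X <- matrix(stats::rnorm(n * 2), n, 2)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(y)) < 2) y[1] <- -y[2]
  list(X = X, y = y,
       table = data.frame(f1 = X[, 1], f2 = X[, 2], label = y))
}

dual_obj <- function(K, y, a) sum(a) - 0.5 * drop((a * y) %*% K %*% (a * y))

# independent QP solution of the SVM dual via kernlab::ipop; near-singular
# kernel matrices need a looser interior-point setting plus a tiny ridge
qp_oracle <- function(K, y, C) {
  n <- length(y)
  settings <- list(c(sigf = 9, margin = 0.05, ridge = 1e-10),
                   c(sigf = 7, margin = 0.05, ridge = 1e-8),
                   c(sigf = 7, margin = 0.10, ridge = 1e-6),
                   c(sigf = 6, margin = 0.20, ridge = 1e-5))
  for (cfg in settings) {
    H <- (y %o% y) * K + diag(cfg[["ridge"]], n)
    fit <- tryCatch(
      kernlab::ipop(c = rep(-1, n), H = H, A = t(y), b = 0, l = rep(0, n),
                    u = rep(C, n), r = 0, sigf = cfg[["sigf"]],
                    margin = cfg[["margin"]], maxiter = 400),
      error = function(e) NULL)
    if (!is.null(fit)) return(kernlab::primal(fit))
  }
  stop("QP oracle failed to converge")
}

accuracy_pct <- function(pred, label) 100 * mean(pred == ifelse(label > 0, "high", "low"))
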