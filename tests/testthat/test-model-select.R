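# shared small dataset: short protocol, low noise, well separated classes
msel_runs <- function(n = 3, noise = 0.02, master_seed = 21)
  generate_dataset(n, short_protocol(), short_sensors(noise),
                   master_seed = master_seed)
msel_scheme <- function() segment_scheme(list(Steady = c(70, 110)))

test_that("default grid matches the published 6 x 5 layout", {
  g <- param_grid()
  expect_equal(g$gammas, 2^(-3:1))
  expect_equal(g$Cs, 2^(-3:2))
  expect_error(param_grid(gammas = numeric(0)), "non-empty")
  expect_error(param_grid(gammas = c(1, -1)), "> 0")
})

test_that("leave-one-run-out splits enumerate held-out class pairs without leakage", {
  runs <- generate_dataset(10, short_protocol(), short_sensors(0.05),
                           master_seed = 1)
  splits <- loro_splits(runs)
  expect_length(splits, 100)  # 10 x 10 cross-product
  labels <- vapply(runs, function(r) r$label, character(1))
  for (sp in splits) {
    expect_length(sp$test, 2)
    expect_setequal(labels[sp$test], c("low", "high"))
    expect_length(intersect(sp$train, sp$test), 0)     # no leakage
    expect_setequal(c(sp$train, sp$test), seq_along(runs))
  }
  # every (low, high) pair appears exactly once
  pairs <- vapply(splits, function(sp) paste(sort(sp$test), collapse = "-"),
                  character(1))
  expect_equal(anyDuplicated(pairs), 0L)

  small <- msel_runs(2)
  s4 <- loro_splits(small)
  expect_length(s4, 4)
  for (sp in s4) expect_length(sp$train, 2)  # trains on 1 + 1

  paired <- loro_splits(runs, paired = TRUE)
  expect_length(paired, 10)

  expect_error(loro_splits(runs[c(1, 11:20)]), "at least two runs")
})

test_that("CV accuracy is 100% for noiseless separable classes at small gamma", {
  runs <- msel_runs(3, noise = 0)
  acc <- cv_accuracy(runs, msel_scheme(), "Steady", gamma = 2^-3, C = 1)
  expect_equal(acc, 100)
})

test_that("identical-trace runs give the same accuracy whichever run is held out", {
  # 2 + 2 runs per class, each class's runs cloned from one simulation
  lo <- simulate_run(short_protocol(), short_sensors(0),
                     voc_footprint("low", c(2, 2), c(10, 10)), seed = 1)
  hi <- simulate_run(short_protocol(), short_sensors(0),
                     voc_footprint("high", c(6, 6), c(40, 40)), seed = 2)
  clone <- function(r, id) { r$run_id <- id; r }
  runs <- list(clone(lo, "L1"), clone(lo, "L2"), clone(hi, "H1"), clone(hi, "H2"))
  rows <- lapply(runs, function(r)
    sample_features(r, segment_window(msel_scheme(), "Steady", 60), 5))
  splits <- loro_splits(runs)
  accs <- vapply(splits, function(sp) {
    tr <- do.call(rbind, rows[sp$train]); class(tr) <- c("feature_table", "data.frame")
    te <- do.call(rbind, rows[sp$test])
    fit <- breath_svm(tr, gamma = 0.5, C = 1)
    accuracy_pct(predict(fit, te), te$label)
  }, numeric(1))
  expect_equal(length(unique(accs)), 1L)
})

test_that("reading-level label permutation gives near-chance accuracy", {
  runs <- generate_dataset(10, master_seed = 11)
  tab <- build_design(runs, default_scheme(), "SteadyState", period = 5)
  set.seed(303)
  tab$label <- sample(tab$label)
  ids <- unique(tab$run_id)
  hits <- logical(0)
  for (k in 1:3) {  # three held-out (low, high) run pairs, >= 200 readings
    test_ids <- ids[c(2 * k - 1, 10 + 2 * k)]
    tr <- tab[!tab$run_id %in% test_ids, ]
    te <- tab[tab$run_id %in% test_ids, ]
    class(tr) <- c("feature_table", "data.frame")
    fit <- breath_svm(tr, gamma = 2^-3, C = 1, seed = 1)
    hits <- c(hits, predict(fit, te) == ifelse(te$label > 0, "high", "low"))
  }
  expect_gte(length(hits), 200)
  expect_gt(100 * mean(hits), 40)
  expect_lt(100 * mean(hits), 60)
})

test_that("grid_search fills the matrix, picks the max, and breaks ties low", {
  runs <- msel_runs(3)
  g <- param_grid()
  cv <- grid_search(runs, msel_scheme(), "Steady", grid = g)
  expect_equal(dim(cv$accuracy), c(6, 5))  # 30 evaluated cells
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 100))
  expect_equal(cv$best$accuracy, max(cv$accuracy))
  # separable low-noise data: best accuracy is perfect and the tie rule
  # selects the smallest C then smallest gamma among the tied cells
  tied <- which(abs(cv$accuracy - max(cv$accuracy)) < 1e-9, arr.ind = TRUE)
  best_C <- min(g$Cs[tied[, 1]])
  best_g <- min(g$gammas[tied[tied[, 1] == which(g$Cs == best_C), 2]])
  expect_equal(cv$best$C, best_C)
  expect_equal(cv$best$gamma, best_g)
  expect_error(grid_search(runs, msel_scheme(), "Steady",
                           grid = structure(list(), class = "param_grid")))
})

test_that("grid accuracy is invariant to run ordering", {
  runs <- msel_runs(3)
  small_grid <- param_grid(gammas = c(0.25, 1), Cs = c(0.5, 2))
  a1 <- grid_search(runs, msel_scheme(), "Steady", grid = small_grid)
  a2 <- grid_search(rev(runs), msel_scheme(), "Steady", grid = small_grid)
  expect_equal(unname(a1$accuracy), unname(a2$accuracy))
})

test_that("segment_sweep reports one row per segment with the steady state perfect", {
  runs <- generate_dataset(3, master_seed = 41)  # full-length protocol
  scheme <- segment_scheme(list(Rise = c(65, 85), SteadyState = c(150, 400)))
  small_grid <- param_grid(gammas = c(2^-3, 2^-1), Cs = c(2^-3, 1))
  rep <- segment_sweep(runs, scheme, grid = small_grid, period = 10)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$segment, c("Rise", "SteadyState"))
  expect_equal(rep$accuracy[rep$segment == "SteadyState"], 100)

  one <- segment_sweep(runs, segment_scheme(list(SteadyState = c(150, 400))),
                       grid = small_grid, period = 10)
  expect_equal(nrow(one), 1)

  # export mirrors the tabular layout
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("segment", "gamma", "C", "accuracy"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_report(attr(rep, "results")$SteadyState, path2)
  expect_equal(nrow(utils::read.csv(path2)), 2)
})
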