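# Grid enumeration, metrics, cross-validation, ranking, export, prediction.

test_that("cost and gamma series hit the sweep endpoints exactly", {
  grid <- suppressMessages(make_parameter_grid(grid_spec()))
  costs <- sort(unique(grid$cost))
  gammas <- sort(unique(grid$gamma))
  expect_length(costs, 7)
  expect_length(gammas, 7)
  expect_identical(costs[1], 0.00390625)
  expect_identical(costs[7], 65536)
  expect_identical(gammas[1], 1.52587890625e-5)
  expect_identical(gammas[7], 256)
  expect_equal(costs[-1] / costs[-7], rep(16, 6))

  single <- make_parameter_grid(grid_spec(
    svm_types = "C_SVC", kernels = "LINEAR", c_min = 2, c_max = 2
  ))
  expect_equal(unique(single$cost), 2)

  expect_error(
    make_parameter_grid(grid_spec(
      svm_types = "C_SVC", kernels = "LINEAR", c_min = 1, c_max = 10, c_factor = 16
    )),
    class = "bacsvm_spec_error"
  )
})

test_that("the grid is the ordered Cartesian product and gates PRECOMPUTED", {
  spec <- grid_spec(
    svm_types = c("C_SVC", "NU_SVC"), kernels = "RBF",
    c_min = 1, c_max = 16, c_factor = 16,
    g_min = 0.01, g_max = 0.16, g_factor = 16
  )
  grid <- make_parameter_grid(spec)
  expect_equal(nrow(grid), 8) # 2 types x 1 kernel x 2 C x 2 gamma
  expect_equal(grid$svm_type, rep(c("C_SVC", "NU_SVC"), each = 4))
  expect_true(all(diff(grid$gamma[1:2]) > 0)) # gamma varies fastest

  full <- suppressMessages(make_parameter_grid(grid_spec()))
  expect_equal(nrow(full), 5 * 4 * 7 * 7) # PRECOMPUTED dropped without a Gram
  expect_message(
    make_parameter_grid(grid_spec()),
    "PRECOMPUTED kernel skipped"
  )
  with_gram <- make_parameter_grid(grid_spec(), gram_supplied = TRUE)
  expect_equal(nrow(with_gram), 5 * 5 * 7 * 7)
})

test_that("grid_spec carries the fixed libsvm defaults", {
  spec <- grid_spec()
  expect_equal(spec$degree, 3)
  expect_equal(spec$coef0, 0)
  expect_equal(spec$nu, 0.5)
  expect_equal(spec$cache_mb, 100)
  expect_equal(spec$epsilon, 0.001)
  expect_true(spec$shrinking)
  expect_false(spec$probability)
  expect_equal(spec$class_weight, 1)
  expect_error(grid_spec(c_min = -1), class = "bacsvm_argument_error")
  expect_error(grid_spec(c_factor = 1), class = "bacsvm_argument_error")
})

test_that("metrics match hand-computed values and report undefined as NA", {
  expect_equal(
    classification_metrics(5, 5, 0, 0),
    tibble::tibble(accuracy = 1, specificity = 1, sensitivity = 1)
  )
  expect_equal(
    classification_metrics(3, 4, 1, 2),
    tibble::tibble(accuracy = 0.7, specificity = 0.8, sensitivity = 0.6)
  )
  # degenerate always-negative classifier
  expect_equal(
    classification_metrics(0, 10, 0, 10),
    tibble::tibble(accuracy = 0.5, specificity = 1, sensitivity = 0)
  )
  m <- classification_metrics(3, 0, 0, 2) # no true-negative examples
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 0.6)
  expect_error(classification_metrics(0, 0, 0, 0), class = "bacsvm_argument_error")
  expect_error(classification_metrics(-1, 2, 0, 0), class = "bacsvm_argument_error")
})

test_that("cross-validation is seeded, deterministic and guards its inputs", {
  ds <- generate_benchmark(synth_spec(
    genome_length = 30000, n_promoters = 60, mutation_rate = 0.05, seed = 13
  ), n_negatives = 60)
  a <- cross_validate(ds, "C_SVC", "LINEAR", 1, 0.01, folds = 5, seed = 4)
  b <- cross_validate(ds, "C_SVC", "LINEAR", 1, 0.01, folds = 5, seed = 4)
  expect_identical(a, b)
  expect_equal(a$tp + a$tn + a$fp + a$fn, 120) # every example evaluated once
  expect_equal(
    classification_metrics(a$tp, a$tn, a$fp, a$fn)$accuracy, a$accuracy,
    tolerance = 1e-12
  )

  expect_error(
    cross_validate(ds, "C_SVC", "LINEAR", 1, 0.01, folds = 61, seed = 1),
    class = "bacsvm_argument_error"
  )
  pos_only <- build_dataset(ds$info$seq[ds$info$label == "promoter"])
  expect_error(
    cross_validate(pos_only, "C_SVC", "LINEAR", 1, 0.01, folds = 5, seed = 1),
    class = "bacsvm_argument_error"
  )
  one <- cross_validate(pos_only, "ONE_CLASS", "RBF", 1, 0.01, folds = 5, seed = 1)
  expect_false(one$failed)
  expect_equal(one$tn + one$fp, 0) # no negatives held out
  expect_true(is.na(one$specificity))
})

test_that("regression formulations classify at the 0.5 threshold", {
  ds <- generate_benchmark(synth_spec(
    genome_length = 30000, n_promoters = 60, mutation_rate = 0.02, seed = 14
  ), n_negatives = 60)
  svr <- cross_validate(ds, "EPSILON_SVR", "LINEAR", 1, 0.003125, folds = 5, seed = 4)
  expect_false(svr$failed)
  expect_gte(svr$accuracy, 0.8)
})

test_that("infeasible cells are flagged, not dropped, and rank last", {
  ds <- generate_benchmark(synth_spec(
    genome_length = 20000, n_promoters = 40, mutation_rate = 0.02, seed = 15
  ), n_negatives = 8) # imbalanced: nu = 0.5 is infeasible for NU_SVC
  res <- grid_search(
    ds,
    grid_spec(
      svm_types = c("C_SVC", "NU_SVC"), kernels = "LINEAR",
      c_min = 1, c_max = 1, g_min = 0.01, g_max = 0.01
    ),
    folds = 4, seed = 2
  )
  tidied <- tidy(res)
  expect_equal(nrow(tidied), 2)
  expect_true(any(tidied$failed))
  expect_false(tidied$failed[1]) # failed cells sort last
  expect_true(is.na(tidied$accuracy[tidied$failed]))
})

test_that("grid search ranks by accuracy with declared tie-breaks", {
  ds <- generate_benchmark(synth_spec(
    genome_length = 30000, n_promoters = 60, mutation_rate = 0.05, seed = 16
  ), n_negatives = 60)
  search <- grid_search(ds, reduced_benchmark_spec(), folds = 3, seed = 6)
  r <- tidy(search)
  expect_equal(nrow(r), 18)
  ok <- !r$failed
  expect_true(all(r$accuracy[1] >= r$accuracy[ok]))
  # rank order respects (accuracy desc, sensitivity desc, cost asc, gamma asc)
  key <- order(-r$accuracy, -r$sensitivity, r$cost, r$gamma)
  expect_equal(r$rank[key], sort(r$rank[key]))
  # stored metrics are recomputable from the stored counts
  m <- classification_metrics(r$tp[ok], r$tn[ok], r$fp[ok], r$fn[ok])
  expect_equal(m$accuracy, r$accuracy[ok], tolerance = 1e-12)
  expect_equal(m$specificity, r$specificity[ok], tolerance = 1e-12)
  expect_equal(m$sensitivity, r$sensitivity[ok], tolerance = 1e-12)
  expect_s3_class(autoplot(search), "ggplot")
})

test_that("a supplied Gram matrix enables the PRECOMPUTED kernel", {
  ds <- generate_benchmark(synth_spec(
    genome_length = 20000, n_promoters = 40, mutation_rate = 0.02, seed = 17
  ), n_negatives = 40)
  gram <- tcrossprod(ds$x)
  cv <- cross_validate(ds, "C_SVC", "PRECOMPUTED", 1, 0.01,
    folds = 4, seed = 3, gram = gram
  )
  expect_false(cv$failed)
  expect_gte(cv$accuracy, 0.8) # linear Gram behaves like the linear kernel
  expect_error(
    cross_validate(ds, "C_SVC", "PRECOMPUTED", 1, 0.01, folds = 4, seed = 3),
    class = "bacsvm_argument_error"
  )
})

test_that("label noise degrades the benchmark accuracy monotonically", {
  base <- generate_benchmark(synth_spec(
    genome_length = 30000, n_promoters = 60, mutation_rate = 0.02, seed = 18
  ), n_negatives = 60)
  noisy_accuracy <- function(rate, seed) {
    info <- base$info
    flip <- withr::with_seed(seed, which(stats::runif(nrow(info)) < rate))
    lab <- as.character(info$label)
    lab[flip] <- ifelse(lab[flip] == "promoter", "non_promoter", "promoter")
    ds <- build_dataset(info$seq[lab == "promoter"], info$seq[lab == "non_promoter"])
    cross_validate(ds, "C_SVC", "LINEAR", 1, 0.01, folds = 5, seed = seed)$accuracy
  }
  acc <- vapply(
    c(0, 0.1, 0.3),
    function(rate) mean(vapply(1:3, function(s) noisy_accuracy(rate, s), numeric(1))),
    numeric(1)
  )
  expect_true(all(diff(acc) <= 0))
})

test_that("results export at printed precision and re-parse identically", {
  ds <- generate_benchmark(synth_spec(
    genome_length = 20000, n_promoters = 40, mutation_rate = 0.05, seed = 19
  ), n_negatives = 40)
  search <- grid_search(
    ds,
    grid_spec(
      svm_types = "C_SVC", kernels = c("LINEAR", "RBF", "SIGMOID"),
      c_min = 1, c_max = 1, g_min = 0.01, g_max = 0.01
    ),
    folds = 4, seed = 7
  )
  tf <- withr::local_tempfile(fileext = ".csv")
  export_results(search, tf)
  lines <- readLines(tf)
  expect_length(lines, 4) # header + 3 rows
  expect_equal(lines[1], "Type,Kernel,C,G,A,S,SN,TP,TN,FP,FN")

  fake <- tidy(search)[1, ]
  fake$accuracy <- 0.7
  export_results(fake, tf)
  expect_match(readLines(tf)[2], ",70\\.00,")

  export_results(search, tf)
  back <- read_results(tf)
  r <- tidy(search)
  expect_equal(back$cost, r$cost)
  expect_equal(back$gamma, r$gamma)
  expect_equal(back$accuracy, round(r$accuracy, 4), tolerance = 1e-9)
  expect_equal(back$tp, r$tp)
  # identical runs export byte-identical files
  tf2 <- withr::local_tempfile(fileext = ".csv")
  export_results(grid_search(ds, search$spec, folds = 4, seed = 7), tf2)
  expect_identical(readLines(tf2), readLines(tf))
})

test_that("final models predict, persist and enforce their encoding contract", {
  sim <- generate_genome(synth_spec(
    genome_length = 30000, n_promoters = 60, mutation_rate = 0, seed = 20
  ))
  rep <- extract_promoters(sim$genome, sim$records)
  neg <- sample_negatives(sim$genome, rep, 60, seed = 1)
  ds <- build_dataset(rep, neg)
  model <- train_final(ds, "C_SVC", "LINEAR", 1, 0.01)

  pred <- predict(model, rep$windows$seq[1:5])
  expect_equal(as.character(pred$label), rep("promoter", 5))

  withr::local_seed(3)
  random_seqs <- vapply(rep(80, 100), random_dna_string, character(1))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(model, tf)
  expect_true(file.exists(paste0(tf, ".yml")))
  reloaded <- load_model(tf)
  expect_equal(predict(reloaded, random_seqs), predict(model, random_seqs))

  err <- expect_error(
    predict(model, rep$windows$seq[1:2], encoding = feature_encoding("kmer", k = 3)),
    class = "bacsvm_contract_error"
  )
  expect_match(conditionMessage(err), "onehot")
  expect_match(conditionMessage(err), "kmer")
  expect_error(
    predict(model, "ACGT"),
    class = "bacsvm_contract_error"
  )
})
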