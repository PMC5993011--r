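# Hyperparameter grid enumeration, cross-validated SVM evaluation,
# confusion-matrix metrics, ranking and export.

.svm_types <- c("C_SVC", "NU_SVC", "ONE_CLASS", "EPSILON_SVR", "NU_SVR")
.svm_kernels <- c("LINEAR", "POLY", "RBF", "SIGMOID", "PRECOMPUTED")

#' Specify an SVM hyperparameter grid
#'
#' Defaults reproduce the exhaustive sweep used for bacterial promoter
#' prediction: every combination of the five libsvm formulations and five
#' kernels, cost from 0.00390625 to 65536 and gamma from 1.52587890625e-5
#' to 256, each as a geometric series with multiplicative factor 16 (7
#' values per parameter). The remaining parameters are pinned at the libsvm
#' defaults: degree 3, coef0 0, nu 0.5, cache 100 MB, termination epsilon
#' 0.001, shrinking on, probability estimates off, class weight 1.
#'
#' @param svm_types Subset of `C_SVC`, `NU_SVC`, `ONE_CLASS`,
#'   `EPSILON_SVR`, `NU_SVR`.
#' @param kernels Subset of `LINEAR`, `POLY`, `RBF`, `SIGMOID`,
#'   `PRECOMPUTED`.
#' @param c_min,c_max,c_factor Cost series: geometric from `c_min` by
#'   `c_factor` up to `c_max` (endpoints exact).
#' @param g_min,g_max,g_factor Gamma series, same construction.
#' @param degree,coef0,nu,cache_mb,epsilon,shrinking,probability,class_weight
#'   Fixed libsvm parameters.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(svm_types = .svm_types,
                      kernels = .svm_kernels,
                      c_min = 0.00390625, c_max = 65536, c_factor = 16,
                      g_min = 1.52587890625e-5, g_max = 256, g_factor = 16,
                      degree = 3, coef0 = 0, nu = 0.5, cache_mb = 100,
                      epsilon = 0.001, shrinking = TRUE, probability = FALSE,
                      class_weight = 1) {
  svm_types <- match.arg(svm_types, .svm_types, several.ok = TRUE)
  kernels <- match.arg(kernels, .svm_kernels, several.ok = TRUE)
  if (c_min <= 0 || g_min <= 0 || c_min > c_max || g_min > g_max) {
    abort("parameter ranges must be positive with min <= max",
      class = "bacsvm_argument_error"
    )
  }
  if (c_factor <= 1 || g_factor <= 1) {
    abort("multiplicative factors must exceed 1", class = "bacsvm_argument_error")
  }
  structure(
    list(
      svm_types = svm_types, kernels = kernels,
      c_min = c_min, c_max = c_max, c_factor = c_factor,
      g_min = g_min, g_max = g_max, g_factor = g_factor,
      degree = degree, coef0 = coef0, nu = nu, cache_mb = cache_mb,
      epsilon = epsilon, shrinking = shrinking, probability = probability,
      class_weight = class_weight
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d type(s) x %d kernel(s); C %g..%g (x%g), gamma %g..%g (x%g)\n",
    length(x$svm_types), length(x$kernels), x$c_min, x$c_max, x$c_factor,
    x$g_min, x$g_max, x$g_factor
  ))
  invisible(x)
}

# Geometric series from lo to hi by factor; hi must be reachable within a
# relative tolerance of 1e-9, and both endpoints are snapped exactly.
.geom_series <- function(lo, hi, factor, what) {
  if (lo == hi) {
    return(lo)
  }
  k <- round(log(hi / lo) / log(factor))
  if (k < 1 || abs(lo * factor^k - hi) > 1e-9 * hi) {
    abort(
      sprintf(
        "%s_max (%g) is not reachable from %s_min (%g) by factor %g",
        what, hi, what, lo, factor
      ),
      class = "bacsvm_spec_error"
    )
  }
  vals <- lo * factor^(0:k)
  vals[1] <- lo
  vals[k + 1] <- hi
  vals
}

#' Enumerate the hyperparameter grid
#'
#' Cartesian product of formulations, kernels and the cost/gamma geometric
#' series, in deterministic order (types, then kernels, then ascending
#' cost, then ascending gamma). `PRECOMPUTED` cells are emitted only when a
#' Gram matrix accompanies the sweep; otherwise they are skipped with a
#' notice.
#'
#' @param spec A [grid_spec()].
#' @param gram_supplied Is a precomputed Gram matrix available?
#' @return A tibble with columns `svm_type`, `kernel`, `cost`, `gamma`.
#' @export
make_parameter_grid <- function(spec = grid_spec(), gram_supplied = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  kernels <- spec$kernels
  if ("PRECOMPUTED" %in% kernels && !gram_supplied) {
    inform("PRECOMPUTED kernel skipped: no Gram matrix supplied")
    kernels <- setdiff(kernels, "PRECOMPUTED")
  }
  if (length(kernels) == 0L || length(spec$svm_types) == 0L) {
    abort("empty grid", class = "bacsvm_argument_error")
  }
  costs <- .geom_series(spec$c_min, spec$c_max, spec$c_factor, "c")
  gammas <- .geom_series(spec$g_min, spec$g_max, spec$g_factor, "g")
  tidyr::expand_grid(
    svm_type = factor(spec$svm_types, levels = spec$svm_types),
    kernel = factor(kernels, levels = kernels),
    cost = costs,
    gamma = gammas
  ) |>
    mutate(svm_type = as.character(.data$svm_type), kernel = as.character(.data$kernel))
}

#' Accuracy, specificity and sensitivity from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, specificity `TN/(TN+FP)` and
#' sensitivity `TP/(TP+FN)`, with the promoter class as positive. A metric
#' whose denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (vectorised).
#' @return A tibble with columns `accuracy`, `specificity`, `sensitivity`.
#' @examples
#' classification_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  tp <- unname(tp)
  tn <- unname(tn)
  fp <- unname(fp)
  fn <- unname(fn)
  n <- tp + tn + fp + fn
  if (any(c(tp, tn, fp, fn) < 0, na.rm = TRUE)) {
    abort("confusion counts must be non-negative", class = "bacsvm_argument_error")
  }
  if (any(n == 0, na.rm = TRUE)) {
    abort("confusion counts are all zero", class = "bacsvm_argument_error")
  }
  tibble(
    accuracy = (tp + tn) / n,
    specificity = ifelse(tn + fp > 0, tn / (tn + fp), NA_real_),
    sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  )
}

.e1071_type <- c(
  C_SVC = "C-classification", NU_SVC = "nu-classification",
  ONE_CLASS = "one-classification", EPSILON_SVR = "eps-regression",
  NU_SVR = "nu-regression"
)
.e1071_kernel <- c(
  LINEAR = "linear", POLY = "polynomial", RBF = "radial", SIGMOID = "sigmoid"
)
.ksvm_type <- c(
  C_SVC = "C-svc", NU_SVC = "nu-svc", ONE_CLASS = "one-svc",
  EPSILON_SVR = "eps-svr", NU_SVR = "nu-svr"
)

# Fit one cell and predict the held-out rows; returns a logical vector
# "predicted promoter". For PRECOMPUTED, `gram` is the full n x n matrix
# aligned with the dataset rows and train/test are row indices into it.
.fit_predict <- function(x, y, train, test, svm_type, kernel, cost, gamma,
                         spec, gram = NULL) {
  is_svr <- svm_type %in% c("EPSILON_SVR", "NU_SVR")
  if (svm_type == "ONE_CLASS") train <- train[y[train] == "promoter"]

  if (kernel == "PRECOMPUTED") {
    if (is.null(gram)) {
      abort("PRECOMPUTED kernel requires a Gram matrix", class = "bacsvm_argument_error")
    }
    ytr <- if (is_svr) {
      as.numeric(y[train] == "promoter")
    } else if (svm_type == "ONE_CLASS") {
      NULL
    } else {
      y[train]
    }
    ktr <- kernlab::as.kernelMatrix(gram[train, train, drop = FALSE])
    fit <- if (svm_type == "ONE_CLASS") {
      kernlab::ksvm(ktr, type = "one-svc", nu = spec$nu, eps = spec$epsilon)
    } else {
      kernlab::ksvm(
        ktr, ytr,
        type = .ksvm_type[[svm_type]], C = cost, nu = spec$nu,
        epsilon = 0.1, eps = spec$epsilon
      )
    }
    kte <- kernlab::as.kernelMatrix(
      gram[test, train, drop = FALSE][, kernlab::SVindex(fit), drop = FALSE]
    )
    pred <- kernlab::predict(fit, kte)
    return(
      if (is_svr) {
        as.numeric(pred) >= 0.5
      } else if (svm_type == "ONE_CLASS") {
        as.logical(pred)
      } else {
        as.character(pred) == "promoter"
      }
    )
  }

  ytr <- if (is_svr) as.numeric(y[train] == "promoter") else y[train]
  args <- list(
    x = x[train, , drop = FALSE],
    type = .e1071_type[[svm_type]], kernel = .e1071_kernel[[kernel]],
    cost = cost, gamma = gamma, degree = spec$degree, coef0 = spec$coef0,
    nu = spec$nu, cachesize = spec$cache_mb, tolerance = spec$epsilon,
    shrinking = spec$shrinking, scale = FALSE
  )
  if (svm_type != "ONE_CLASS") args$y <- ytr
  fit <- do.call(e1071::svm, args)
  pred <- predict(fit, x[test, , drop = FALSE])
  if (is_svr) {
    as.numeric(pred) >= 0.5
  } else if (svm_type == "ONE_CLASS") {
    as.logical(pred)
  } else {
    as.character(pred) == "promoter"
  }
}

# Seeded stratified fold assignment: within each class, examples are
# shuffled and dealt round-robin into `folds` folds.
.stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) == 0L) next
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

#' Cross-validate one grid cell
#'
#' Seeded stratified k-fold cross-validation of a single (formulation,
#' kernel, cost, gamma) cell. Confusion counts are pooled over the held-out
#' folds with `promoter` as the positive class. The one-class formulation
#' trains on the training fold's promoters only and predicts the full
#' held-out fold; the regression formulations fit labels encoded 0/1 and
#' classify at threshold 0.5. Identical inputs and seed give identical
#' results.
#'
#' @param dataset A `promoter_dataset` from [build_dataset()].
#' @param svm_type One of `C_SVC`, `NU_SVC`, `ONE_CLASS`, `EPSILON_SVR`,
#'   `NU_SVR`.
#' @param kernel One of `LINEAR`, `POLY`, `RBF`, `SIGMOID`, `PRECOMPUTED`.
#' @param cost,gamma Cell parameters.
#' @param folds Number of folds (>= 2, at most the minority class size).
#' @param seed Integer seed for the fold assignment.
#' @param spec A [grid_spec()] supplying the fixed libsvm parameters.
#' @param gram Full Gram matrix aligned with the dataset rows
#'   (`PRECOMPUTED` kernel only).
#' @return A one-row tibble: the cell, pooled `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `specificity`, `sensitivity`, `folds`, `seed`, and a
#'   `failed` flag (with `note`) for cells whose fit did not converge.
#' @export
cross_validate <- function(dataset, svm_type, kernel, cost, gamma,
                           folds = 10, seed = 0, spec = grid_spec(),
                           gram = NULL) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  svm_type <- match.arg(svm_type, .svm_types)
  kernel <- match.arg(kernel, .svm_kernels)
  if (kernel == "PRECOMPUTED" && is.null(gram)) {
    abort("PRECOMPUTED kernel requires a Gram matrix", class = "bacsvm_argument_error")
  }
  y <- dataset$info$label
  n_pos <- sum(y == "promoter")
  n_neg <- sum(y == "non_promoter")
  if (svm_type != "ONE_CLASS" && (n_pos == 0L || n_neg == 0L)) {
    abort("two-class formulations need both classes in the dataset",
      class = "bacsvm_argument_error"
    )
  }
  min_class <- if (n_neg == 0L) n_pos else min(n_pos, n_neg)
  if (folds < 2 || folds > min_class) {
    abort(
      sprintf("folds must be in [2, %d] for this dataset", min_class),
      class = "bacsvm_argument_error"
    )
  }

  fold <- .stratified_folds(y, folds, seed)
  cell <- tibble(svm_type = svm_type, kernel = kernel, cost = cost, gamma = gamma)

  counts <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  failure <- NULL
  for (f in seq_len(folds)) {
    train <- which(fold != f)
    test <- which(fold == f)
    pred_pos <- tryCatch(
      .fit_predict(
        dataset$x, y, train, test, svm_type, kernel, cost, gamma, spec, gram
      ),
      error = function(e) e
    )
    if (inherits(pred_pos, "error")) {
      failure <- conditionMessage(pred_pos)
      break
    }
    truth_pos <- y[test] == "promoter"
    counts["tp"] <- counts["tp"] + sum(pred_pos & truth_pos)
    counts["tn"] <- counts["tn"] + sum(!pred_pos & !truth_pos)
    counts["fp"] <- counts["fp"] + sum(pred_pos & !truth_pos)
    counts["fn"] <- counts["fn"] + sum(!pred_pos & truth_pos)
  }

  if (!is.null(failure)) {
    return(dplyr::bind_cols(cell, tibble(
      tp = NA_integer_, tn = NA_integer_, fp = NA_integer_, fn = NA_integer_,
      accuracy = NA_real_, specificity = NA_real_, sensitivity = NA_real_,
      folds = as.integer(folds), seed = as.integer(seed),
      failed = TRUE, note = failure
    )))
  }
  m <- classification_metrics(counts["tp"], counts["tn"], counts["fp"], counts["fn"])
  dplyr::bind_cols(
    cell,
    tibble(
      tp = counts[["tp"]], tn = counts[["tn"]],
      fp = counts[["fp"]], fn = counts[["fn"]]
    ),
    m,
    tibble(
      folds = as.integer(folds), seed = as.integer(seed),
      failed = FALSE, note = NA_character_
    )
  )
}

#' Exhaustive grid search over SVM formulations, kernels, cost and gamma
#'
#' Evaluates every cell of the grid by [cross_validate()] and ranks the
#' results by descending accuracy, ties broken by descending sensitivity,
#' then ascending cost, then ascending gamma. Cells whose fit fails (e.g.
#' an infeasible nu for the class ratio) are kept with a failure flag and
#' sort last, so the sweep always completes.
#'
#' @inheritParams cross_validate
#' @param spec A [grid_spec()] defining the sweep.
#' @return An object of class `svm_grid_search`; `tidy()` gives the ranked
#'   per-cell tibble, `glance()` a one-row summary, `autoplot()` an
#'   accuracy heat map over the cost/gamma plane.
#' @export
grid_search <- function(dataset, spec = grid_spec(), folds = 10, seed = 0,
                        gram = NULL) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  grid <- make_parameter_grid(spec, gram_supplied = !is.null(gram))
  results <- pmap(grid, function(svm_type, kernel, cost, gamma) {
    cross_validate(
      dataset, svm_type, kernel, cost, gamma,
      folds = folds, seed = seed, spec = spec, gram = gram
    )
  }) |> list_rbind()
  results <- arrange(
    results, .data$failed, desc(.data$accuracy), desc(.data$sensitivity),
    .data$cost, .data$gamma
  ) |> mutate(rank = row_number(), .before = 1)
  structure(
    list(results = results, spec = spec, folds = folds, seed = seed),
    class = "svm_grid_search"
  )
}

#' @export
print.svm_grid_search <- function(x, ...) {
  cat(sprintf(
    "<svm_grid_search> %d cell(s), %d-fold CV (seed %d), %d failed\n",
    nrow(x$results), x$folds, x$seed, sum(x$results$failed)
  ))
  print(head(x$results, 5))
  invisible(x)
}

#' @describeIn grid_search Ranked per-cell results.
#' @param x An `svm_grid_search`.
#' @param ... Unused.
#' @method tidy svm_grid_search
#' @export
tidy.svm_grid_search <- function(x, ...) x$results

#' @describeIn grid_search One-row summary with the best cell.
#' @method glance svm_grid_search
#' @export
glance.svm_grid_search <- function(x, ...) {
  best <- x$results[1, ]
  tibble(
    n_cells = nrow(x$results),
    n_failed = sum(x$results$failed),
    folds = as.integer(x$folds),
    seed = as.integer(x$seed),
    best_svm_type = best$svm_type,
    best_kernel = best$kernel,
    best_cost = best$cost,
    best_gamma = best$gamma,
    best_accuracy = best$accuracy,
    best_specificity = best$specificity,
    best_sensitivity = best$sensitivity
  )
}

#' @describeIn grid_search Accuracy heat map over the log2 cost/gamma plane,
#'   faceted by formulation and kernel.
#' @param object An `svm_grid_search`.
#' @method autoplot svm_grid_search
#' @export
autoplot.svm_grid_search <- function(object, ...) {
  d <- filter(object$results, !.data$failed)
  ggplot2::ggplot(d, ggplot2::aes(
    x = log2(.data$cost), y = log2(.data$gamma), fill = .data$accuracy
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$svm_type),
      cols = ggplot2::vars(.data$kernel)
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = "log2 C", y = "log2 gamma", fill = "accuracy",
      title = "Cross-validated accuracy over the hyperparameter grid"
    ) +
    ggplot2::theme_minimal()
}

#' Export grid-search results as CSV
#'
#' Columns `Type,Kernel,C,G,A,S,SN,TP,TN,FP,FN`; accuracy, specificity and
#' sensitivity are printed as percentages with two decimals. Re-parsing
#' with [read_results()] reproduces the values exactly at the printed
#' precision, and two identical runs produce byte-identical files.
#'
#' @param results An `svm_grid_search` or its `tidy()` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_results <- function(results, path) {
  if (inherits(results, "svm_grid_search")) results <- results$results
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) {
    abort("no results to export", class = "bacsvm_argument_error")
  }
  pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", 100 * x))
  num <- function(x) vapply(x, as.character, character(1))
  out <- tibble(
    Type = results$svm_type,
    Kernel = results$kernel,
    C = num(results$cost),
    G = num(results$gamma),
    A = pct(results$accuracy),
    S = pct(results$specificity),
    SN = pct(results$sensitivity),
    TP = results$tp, TN = results$tn, FP = results$fp, FN = results$fn
  )
  tryCatch(
    readr::write_csv(out, path, progress = FALSE, na = "NA"),
    error = function(e) {
      abort(paste0("cannot write results CSV: ", path), class = "bacsvm_io_error")
    }
  )
  invisible(path)
}

#' Read a results CSV written by [export_results()]
#'
#' @param path Input CSV path.
#' @return A tibble with numeric `cost`, `gamma`, fractional `accuracy`,
#'   `specificity`, `sensitivity` and integer confusion counts, in file
#'   order.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot open results CSV: ", path), class = "bacsvm_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      Type = readr::col_character(), Kernel = readr::col_character(),
      C = readr::col_double(), G = readr::col_double(),
      A = readr::col_double(), S = readr::col_double(), SN = readr::col_double(),
      TP = readr::col_integer(), TN = readr::col_integer(),
      FP = readr::col_integer(), FN = readr::col_integer()
    ),
    progress = FALSE, na = "NA"
  )
  tibble(
    svm_type = raw$Type, kernel = raw$Kernel, cost = raw$C, gamma = raw$G,
    accuracy = raw$A / 100, specificity = raw$S / 100, sensitivity = raw$SN / 100,
    tp = raw$TP, tn = raw$TN, fp = raw$FP, fn = raw$FN
  )
}

#' Train a final model on the full dataset
#'
#' Fits the chosen grid cell on every example (promoters only for the
#' one-class formulation) and wraps it with the dataset's encoding
#' descriptor so predictions are contract-checked.
#'
#' @inheritParams cross_validate
#' @return An object of class `promoter_svm`.
#' @export
train_final <- function(dataset, svm_type, kernel, cost, gamma,
                        spec = grid_spec()) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  svm_type <- match.arg(svm_type, .svm_types)
  kernel <- match.arg(kernel, setdiff(.svm_kernels, "PRECOMPUTED"))
  y <- dataset$info$label
  is_svr <- svm_type %in% c("EPSILON_SVR", "NU_SVR")
  train <- if (svm_type == "ONE_CLASS") which(y == "promoter") else seq_along(y)
  ytr <- if (is_svr) as.numeric(y[train] == "promoter") else y[train]
  args <- list(
    x = dataset$x[train, , drop = FALSE],
    type = .e1071_type[[svm_type]], kernel = .e1071_kernel[[kernel]],
    cost = cost, gamma = gamma, degree = spec$degree, coef0 = spec$coef0,
    nu = spec$nu, cachesize = spec$cache_mb, tolerance = spec$epsilon,
    shrinking = spec$shrinking, scale = FALSE
  )
  if (svm_type != "ONE_CLASS") args$y <- ytr
  fit <- do.call(e1071::svm, args)
  structure(
    list(
      model = fit, svm_type = svm_type, kernel = kernel,
      cost = cost, gamma = gamma, encoding = dataset$encoding
    ),
    class = "promoter_svm"
  )
}

#' @export
print.promoter_svm <- function(x, ...) {
  cat(sprintf(
    "<promoter_svm> %s + %s (C=%g, gamma=%g); %s encoding, window %d nt\n",
    x$svm_type, x$kernel, x$cost, x$gamma, x$encoding$scheme,
    x$encoding$window_length
  ))
  invisible(x)
}

.encoding_descr <- function(e) {
  sprintf(
    "%s(k=%s, window=%s)", e$scheme,
    ifelse(is.na(e$k), "-", e$k), ifelse(is.na(e$window_length), "-", e$window_length)
  )
}

#' Predict promoter labels for new sequences
#'
#' Sequences are encoded with the model's own encoding descriptor; an
#' explicitly supplied `encoding` must match it exactly (scheme, k, window
#' length), otherwise a contract error names both descriptors.
#'
#' @param object A `promoter_svm` from [train_final()].
#' @param new_data Character vector of DNA strings, a tibble with `id` and
#'   `seq` columns, or an `extraction_report`.
#' @param encoding Optional [feature_encoding()] asserting how `new_data`
#'   should be encoded.
#' @param ... Unused.
#' @return A tibble with columns `id` and `label`
#'   (`promoter`/`non_promoter`), one row per input sequence.
#' @export
predict.promoter_svm <- function(object, new_data, encoding = NULL, ...) {
  seqs <- .seq_chr(new_data)
  if (length(seqs) == 0L) {
    abort("no sequences to predict", class = "bacsvm_argument_error")
  }
  if (!is.null(encoding)) {
    same <- identical(encoding$scheme, object$encoding$scheme) &&
      identical(encoding$k, object$encoding$k) &&
      (is.na(encoding$window_length) ||
        identical(encoding$window_length, object$encoding$window_length))
    if (!same) {
      abort(
        sprintf(
          "encoding mismatch: model was trained with %s but input declares %s",
          .encoding_descr(object$encoding), .encoding_descr(encoding)
        ),
        class = "bacsvm_contract_error"
      )
    }
  }
  if (any(nchar(seqs) != object$encoding$window_length)) {
    abort(
      sprintf(
        "sequence length %d does not match the model window length %d",
        nchar(seqs)[which(nchar(seqs) != object$encoding$window_length)[1]],
        object$encoding$window_length
      ),
      class = "bacsvm_contract_error"
    )
  }
  x <- encode_sequences(seqs, object$encoding)
  pred <- predict(object$model, x)
  lab <- if (object$svm_type %in% c("EPSILON_SVR", "NU_SVR")) {
    as.numeric(pred) >= 0.5
  } else if (object$svm_type == "ONE_CLASS") {
    as.logical(pred)
  } else {
    as.character(pred) == "promoter"
  }
  tibble(
    id = names(seqs) %||% sprintf("seq_%04d", seq_along(seqs)),
    label = factor(
      ifelse(lab, "promoter", "non_promoter"),
      levels = c("promoter", "non_promoter")
    )
  )
}

#' Save / load a trained promoter model
#'
#' The model is serialised to `path` with a plain-text YAML sidecar
#' (`<path>.yml`) recording the grid cell and encoding descriptor, so a
#' loaded model predicts identically to the in-memory one and its contract
#' survives the round trip.
#'
#' @param object A `promoter_svm`.
#' @param path Destination path (e.g. `model.rds`).
#' @return `path` (`save_model`) or the restored `promoter_svm`
#'   (`load_model`), invisibly for the former.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "promoter_svm"))
  saveRDS(object, path)
  yaml::write_yaml(
    list(
      svm_type = object$svm_type, kernel = object$kernel,
      cost = object$cost, gamma = object$gamma,
      encoding = list(
        scheme = object$encoding$scheme,
        k = if (is.na(object$encoding$k)) NULL else object$encoding$k,
        window_length = object$encoding$window_length,
        dimension = object$encoding$dimension
      )
    ),
    paste0(path, ".yml")
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot open model file: ", path), class = "bacsvm_io_error")
  }
  object <- readRDS(path)
  if (!inherits(object, "promoter_svm")) {
    abort("file does not contain a promoter_svm model", class = "bacsvm_format_error")
  }
  object
}
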