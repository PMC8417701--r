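#' Adjusted chance level for binary classification
#'
#' The smallest accuracy that exceeds random guessing at significance
#' `alpha` given `n_trials` test trials: `k*/n_trials`, where `k*` is the
#' smallest count with `Binomial(n_trials, 0.5)` CDF at least
#' `1 - alpha`. Decision thresholds adjusted this way shrink toward 0.5
#' as the amount of test data grows.
#'
#' @param n_trials number of test trials (>= 1).
#' @param alpha significance level in (0, 1).
#' @return Object of class `chance_level` with fields `n_trials`,
#'   `alpha`, `level`.
#' @export
adjusted_chance_level <- function(n_trials, alpha = 0.05) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  k_star <- qbinom(1 - alpha, n_trials, 0.5)
  structure(list(n_trials = n_trials, alpha = alpha,
                 level = k_star / n_trials), class = "chance_level")
}

#' @export
print.chance_level <- function(x, ...) {
  cat(sprintf("adjusted chance level: %.4f (n = %d, alpha = %g)\n",
              x$level, x$n_trials, x$alpha))
  invisible(x)
}

# rows usable for a feature set: finite in every feature column
complete_rows <- function(tbl, features) {
  if (!all(features %in% names(tbl))) return(tbl[0, ])
  keep <- complete.cases(tbl[, features, drop = FALSE])
  tbl[keep, , drop = FALSE]
}

#' Time-separated split of one participant's feature table
#'
#' Training data are the participant's first LOW and first HIGH task
#' blocks, testing data the remaining two. Within each phase x condition
#' the epochs (time-ordered) are cut into three contiguous subsets S1-S3
#' of near-equal size, from which the overlapping groups G1 = S1+S2,
#' G2 = S2+S3, G3 = S3+S1 are formed; every epoch belongs to exactly two
#' groups.
#'
#' @param tbl one participant's feature table (see [extract_features()]).
#' @return Object of class `ecological_split`: for each phase
#'   (`train`, `test`) and condition, the subset and group row indices
#'   into `tbl`, plus a `time_separation` audit table.
#' @export
make_ecological_split <- function(tbl) {
  task <- tbl[tbl$condition %in% c("LOW", "HIGH"), ]
  block_start <- aggregate(task$start_time,
                           list(block = task$block_index,
                                condition = task$condition), min)
  if (nrow(block_start) < 4)
    stop("participant must have 4 task blocks (2 LOW, 2 HIGH)")
  pick <- function(cond, which_one) {
    b <- block_start[block_start$condition == cond, ]
    b <- b[order(b$x), ]
    b$block[which_one]
  }
  phase_block <- list(
    train = c(LOW = pick("LOW", 1), HIGH = pick("HIGH", 1)),
    test = c(LOW = pick("LOW", 2), HIGH = pick("HIGH", 2)))
  thirds <- function(idx) {
    n <- length(idx)
    sz <- rep(n %/% 3, 3)
    extra <- n %% 3
    if (extra >= 1) sz[1] <- sz[1] + 1
    if (extra >= 2) sz[2] <- sz[2] + 1
    split(idx, rep(1:3, times = sz))
  }
  out <- list()
  audit <- list()
  for (phase in c("train", "test")) {
    for (cond in c("LOW", "HIGH")) {
      rows <- which(tbl$block_index == phase_block[[phase]][[cond]])
      rows <- rows[order(tbl$start_time[rows])]
      S <- thirds(rows)
      out[[phase]][[cond]] <- list(
        S = S, G = list(G1 = c(S[[1]], S[[2]]), G2 = c(S[[2]], S[[3]]),
                        G3 = c(S[[3]], S[[1]])))
    }
  }
  for (cond in c("LOW", "HIGH")) {
    tr <- unlist(out$train[[cond]]$S)
    te <- unlist(out$test[[cond]]$S)
    audit[[cond]] <- data.frame(
      condition = cond,
      max_train_time = max(tbl$start_time[tr]),
      min_test_time = min(tbl$start_time[te]))
  }
  audit <- do.call(rbind, audit)
  audit$ok <- audit$max_train_time < audit$min_test_time
  structure(c(out, list(time_separation = audit)),
            class = "ecological_split")
}

#' Check the time-separation invariant of an ecological split
#'
#' @param split an `ecological_split`, or an object carrying a
#'   `time_separation` audit attribute (ecological benchmark results).
#' @return `TRUE` when every training epoch precedes every testing epoch
#'   of the same condition; otherwise `FALSE`.
#' @export
check_time_separation <- function(split) {
  audit <- if (inherits(split, "ecological_split")) split$time_separation
           else attr(split, "time_separation")
  if (is.null(audit)) stop("no time-separation audit found")
  all(audit$ok)
}

#' Enumerate train/test group combinations of an ecological split
#'
#' One training combination pairs one LOW group with one HIGH group from
#' the training phase (9 combinations); test combinations likewise (9);
#' their Cartesian product gives the 81 evaluations. Enumeration order is
#' fixed (train-major, LOW index fastest within phase) so runs replay
#' deterministically.
#'
#' @param split an `ecological_split`.
#' @param n_groups groups per phase x condition (3; exposed for testing).
#' @return List with data frames `train_combos`, `test_combos`, `pairs`.
#' @export
enumerate_train_test_pairs <- function(split, n_groups = 3) {
  combos <- expand.grid(low = seq_len(n_groups), high = seq_len(n_groups))
  combos <- combos[order(combos$low, combos$high), c("low", "high")]
  rownames(combos) <- NULL
  pairs <- expand.grid(test_idx = seq_len(nrow(combos)),
                       train_idx = seq_len(nrow(combos)))
  pairs <- pairs[order(pairs$train_idx, pairs$test_idx),
                 c("train_idx", "test_idx")]
  rownames(pairs) <- NULL
  list(train_combos = combos, test_combos = combos, pairs = pairs)
}

#' Traditional (time-agnostic) intra-participant cross-validation
#'
#' A seeded, stratified 70% subsample of the participant's epochs tunes
#' hyperparameters by 5-fold grid search; the tuned configuration is then
#' evaluated by stratified 10-fold cross-validation over *all* the
#' participant's epochs (the published procedure, which deliberately lets
#' tuning rows reappear in the evaluation; set `clean = TRUE` to restrict
#' the final folds to rows outside the tuning subsample).
#'
#' @param tbl one participant's feature table.
#' @param features feature column names.
#' @param classifier classifier id.
#' @param seed integer seed (subsample + fold assignment).
#' @param grid hyperparameter grid (default [default_grids()]).
#' @param tune_frac tuning subsample fraction (default 0.7).
#' @param n_folds evaluation folds (default 10).
#' @param clean exclude tuning rows from evaluation (default `FALSE`).
#' @return Numeric vector of fold accuracies with attribute `params`.
#' @export
traditional_intra_cv <- function(tbl, features, classifier, seed = 1L,
                                 grid = default_grids()[[classifier]],
                                 tune_frac = 0.7, n_folds = 10,
                                 clean = FALSE) {
  tbl <- complete_rows(tbl, features)
  x <- as.matrix(tbl[, features, drop = FALSE])
  y <- factor(tbl$condition, levels = c("LOW", "HIGH"))
  if (nlevels(droplevels(y)) < 2) stop("both condition labels required")
  tune_idx <- with_seed(child_seed(seed, "tune"), {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(tune_frac * length(idx)))
    }))
  })
  best <- grid_search_cv(classifier, x[tune_idx, , drop = FALSE],
                         y[tune_idx], grid = grid,
                         seed = child_seed(seed, "grid"))
  eval_idx <- if (clean) setdiff(seq_along(y), tune_idx) else seq_along(y)
  xe <- x[eval_idx, , drop = FALSE]; ye <- droplevels(y[eval_idx])
  fold_id <- stratified_folds(ye, n_folds, seed = child_seed(seed, "folds"))
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    std <- standardizer_fit(xe[tr, , drop = FALSE])
    fit <- fit_classifier(classifier,
                          standardizer_apply(std, xe[tr, , drop = FALSE]),
                          ye[tr], best)
    pred <- predict_classifier(fit,
                               standardizer_apply(std, xe[!tr, , drop = FALSE]))
    acc[f] <- mean(pred == ye[!tr])
  }
  structure(acc, params = best)
}

#' Ecological (time-separated) intra-participant cross-validation
#'
#' For each of the 9 training group combinations: hyperparameters are
#' tuned by 5-fold grid search inside the training combination, the
#' classifier is fitted on it, and accuracy is measured on each of the 9
#' test combinations, yielding 81 scores. Training epochs always precede
#' testing epochs in session time (asserted; audit attached).
#'
#' @inheritParams traditional_intra_cv
#' @return Numeric vector of 81 accuracies (train-major order), with
#'   attributes `pairs` and `time_separation`.
#' @export
ecological_intra_cv <- function(tbl, features, classifier, seed = 1L,
                                grid = default_grids()[[classifier]]) {
  tbl <- complete_rows(tbl, features)
  split <- make_ecological_split(tbl)
  if (!check_time_separation(split))
    stop("time-separation violated in ecological split")
  enum <- enumerate_train_test_pairs(split)
  x <- as.matrix(tbl[, features, drop = FALSE])
  y <- factor(tbl$condition, levels = c("LOW", "HIGH"))
  acc <- numeric(nrow(enum$pairs))
  k <- 0L
  for (tc in seq_len(nrow(enum$train_combos))) {
    gi <- enum$train_combos$low[tc]; gj <- enum$train_combos$high[tc]
    tr_rows <- c(split$train$LOW$G[[gi]], split$train$HIGH$G[[gj]])
    best <- grid_search_cv(classifier, x[tr_rows, , drop = FALSE],
                           droplevels(y[tr_rows]), grid = grid,
                           seed = child_seed(seed, "grid", tc))
    std <- standardizer_fit(x[tr_rows, , drop = FALSE])
    fit <- fit_classifier(classifier,
                          standardizer_apply(std, x[tr_rows, , drop = FALSE]),
                          droplevels(y[tr_rows]), best)
    for (uc in seq_len(nrow(enum$test_combos))) {
      ui <- enum$test_combos$low[uc]; uj <- enum$test_combos$high[uc]
      te_rows <- c(split$test$LOW$G[[ui]], split$test$HIGH$G[[uj]])
      pred <- predict_classifier(fit,
                                 standardizer_apply(std,
                                                    x[te_rows, , drop = FALSE]))
      k <- k + 1L
      acc[k] <- mean(pred == y[te_rows])
    }
  }
  structure(acc, pairs = enum$pairs,
            time_separation = split$time_separation)
}

#' Leave-2-participants-out folds
#'
#' @param participants character vector of participant ids.
#' @param n_out participants held out per fold (default 2).
#' @return List of folds, each a character vector of held-out ids (all
#'   unordered pairs).
#' @export
inter_folds <- function(participants, n_out = 2) {
  if (length(participants) < n_out + 1)
    stop("need at least ", n_out + 1, " participants")
  pairs <- combn(participants, n_out, simplify = FALSE)
  pairs
}

#' Inter-participant cross-validation (traditional and ecological)
#'
#' Traditional: for every unordered participant pair, train on all other
#' participants' full tables (5-fold grid search on the training pool),
#' then test each held-out participant separately. Ecological (partial
#' transfer): the held-out participants' *first* LOW and HIGH blocks join
#' the training pool; only their *last* LOW and HIGH blocks are tested,
#' so each test participant's training rows strictly precede their test
#' rows in session time (audited).
#'
#' @param tables named list of per-participant feature tables.
#' @param features feature column names.
#' @param classifier classifier id.
#' @param design `"traditional"` or `"ecological"`.
#' @param seed integer seed.
#' @param grid hyperparameter grid.
#' @param n_out held-out participants per fold (default 2).
#' @return Data frame with one row per (fold, test participant):
#'   `fold`, `test_participant`, `accuracy`, `n_test`; ecological results
#'   carry a `time_separation` attribute.
#' @export
inter_cv <- function(tables, features, classifier,
                     design = c("traditional", "ecological"), seed = 1L,
                     grid = default_grids()[[classifier]], n_out = 2) {
  design <- match.arg(design)
  tables <- lapply(tables, complete_rows, features = features)
  tables <- tables[vapply(tables, nrow, integer(1)) > 0]
  ids <- names(tables)
  folds <- inter_folds(ids, n_out)
  first_last <- function(tbl) {
    sp <- make_ecological_split(tbl)
    list(first = sort(unique(c(unlist(sp$train$LOW$S), unlist(sp$train$HIGH$S)))),
         last = sort(unique(c(unlist(sp$test$LOW$S), unlist(sp$test$HIGH$S)))))
  }
  res <- list(); audit <- list()
  for (fi in seq_along(folds)) {
    held <- folds[[fi]]
    train_parts <- lapply(tables[setdiff(ids, held)], function(tb)
      tb[, c("condition", features), drop = FALSE])
    test_rows <- list()
    if (design == "ecological") {
      for (p in held) {
        fl <- first_last(tables[[p]])
        train_parts[[p]] <- tables[[p]][fl$first, c("condition", features)]
        test_rows[[p]] <- tables[[p]][fl$last, , drop = FALSE]
        audit[[paste(fi, p)]] <- data.frame(
          fold = fi, participant = p,
          max_train_time = max(tables[[p]]$start_time[fl$first]),
          min_test_time = min(tables[[p]]$start_time[fl$last]))
      }
    } else {
      for (p in held) test_rows[[p]] <- tables[[p]]
    }
    train_tbl <- do.call(rbind, train_parts)
    x <- as.matrix(train_tbl[, features, drop = FALSE])
    y <- factor(train_tbl$condition, levels = c("LOW", "HIGH"))
    best <- grid_search_cv(classifier, x, y, grid = grid,
                           seed = child_seed(seed, "grid", fi))
    std <- standardizer_fit(x)
    fit <- fit_classifier(classifier, standardizer_apply(std, x), y, best)
    for (p in held) {
      xt <- as.matrix(test_rows[[p]][, features, drop = FALSE])
      pred <- predict_classifier(fit, standardizer_apply(std, xt))
      res[[paste(fi, p)]] <- data.frame(
        fold = fi, test_participant = p,
        accuracy = mean(pred == test_rows[[p]]$condition),
        n_test = nrow(xt))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (design == "ecological") {
    ad <- do.call(rbind, audit)
    ad$ok <- ad$max_train_time < ad$min_test_time
    attr(out, "time_separation") <- ad
  }
  out
}

#' Run the full validation benchmark
#'
#' Evaluates every requested (design, scope, feature set, classifier)
#' cell and collects per-evaluation accuracies with their mean and SD —
#' the machine-readable twin of a published benchmark table. Stochastic
#' steps (subsampling, fold assignment) all derive from `seed`, so a
#' replay reproduces every accuracy exactly.
#'
#' @param tables named list of per-participant feature tables.
#' @param designs subset of `c("traditional", "ecological")`.
#' @param scopes subset of `c("intra", "inter")`.
#' @param sets named list of feature-set column vectors (default
#'   [feature_sets()]); participants whose table lacks a set's columns are
#'   skipped for that set.
#' @param classifiers classifier ids (default all 7).
#' @param seed master seed.
#' @param grids hyperparameter grids.
#' @return Data frame of class `validation_outcome` with columns
#'   `design`, `scope`, `feature_set`, `classifier`, `n_eval`, `mean`,
#'   `sd`, and a list column `accuracies`.
#' @export
run_benchmark <- function(tables,
                          designs = c("traditional", "ecological"),
                          scopes = c("intra", "inter"),
                          sets = feature_sets(),
                          classifiers = classifier_ids(),
                          seed = 1L, grids = default_grids()) {
  rows <- list()
  for (design in designs) for (scope in scopes) {
    for (si in seq_along(sets)) {
      feats <- sets[[si]]
      usable <- Filter(function(tb) nrow(complete_rows(tb, feats)) > 0, tables)
      if (!length(usable)) next
      for (cl in classifiers) {
        cell_seed <- child_seed(seed, design, scope, names(sets)[si], cl)
        acc <- tryCatch({
          if (scope == "intra") {
            unlist(lapply(seq_along(usable), function(pi) {
              ps <- child_seed(cell_seed, pi)
              if (design == "traditional")
                as.numeric(traditional_intra_cv(usable[[pi]], feats, cl,
                                                seed = ps, grid = grids[[cl]]))
              else
                as.numeric(ecological_intra_cv(usable[[pi]], feats, cl,
                                               seed = ps, grid = grids[[cl]]))
            }))
          } else {
            inter_cv(usable, feats, cl, design = design, seed = cell_seed,
                     grid = grids[[cl]])$accuracy
          }
        }, error = function(e) {
          warning("cell (", design, ", ", scope, ", ", names(sets)[si], ", ",
                  cl, ") failed: ", conditionMessage(e))
          numeric()
        })
        if (!length(acc)) next
        rows[[length(rows) + 1L]] <- data.frame(
          design = design, scope = scope, feature_set = names(sets)[si],
          classifier = cl, n_eval = length(acc), mean = mean(acc),
          sd = sd(acc))
        rows[[length(rows)]]$accuracies <- list(acc)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_outcome", class(out))
  out
}
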