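#' BEED: boosting ensemble by equalized down-sampling
#'
#' For a binary table with m majority and n minority rows (m >= n), the
#' majority class is shuffled and partitioned into `floor(m/n)` disjoint
#' blocks of size n (the remainder is discarded, with a message); each
#' block joined with the full minority class gives a balanced n:n training
#' subset. One base classifier is fitted per subset. Each member is then
#' scored by its AUC on the union of the *other* subsets (deduplicated),
#' and member weights are the min-max normalisation of those AUCs. At
#' prediction time the members' hard votes are combined as
#' `sum(w_i * vote_i) / sum(w_i)` and the case is called positive when the
#' combined score strictly exceeds the decision criterion (default 0.5).
#'
#' Despite the "boosting" in the name, members are trained in parallel on
#' their subsets and combined by a weighted vote; there is no sequential
#' reweighting across members.
#'
#' @name beed
NULL

#' Partition an imbalanced table into balanced subsets
#'
#' @param majority_ids,minority_ids identifiers of the two classes
#'   (`length(majority_ids) = m`, `length(minority_ids) = n`).
#' @param seed integer seed for the majority shuffle.
#' @return list of id vectors, each of size `2n` with exactly `n` ids per
#'   class; discarded majority ids are attached as attribute
#'   `"discarded"`. When `m < n` a single subset holding everything is
#'   returned with a warning.
#' @examples
#' length(equalized_downsample(1:160, 161:190, seed = 1))  # 5
#' @export
equalized_downsample <- function(majority_ids, minority_ids, seed = 1L) {
  m <- length(majority_ids); n <- length(minority_ids)
  if (m == 0 || n == 0) stop("both classes must be non-empty", call. = FALSE)
  if (m < n) {
    warning("majority class is smaller than minority; returning one subset ",
            "with all data", call. = FALSE)
    out <- list(c(majority_ids, minority_ids))
    attr(out, "discarded") <- majority_ids[0]
    return(out)
  }
  k <- m %/% n
  shuffled <- withr::with_seed(seed, majority_ids[sample.int(m)])
  used <- shuffled[seq_len(k * n)]
  discarded <- shuffled[setdiff(seq_len(m), seq_len(k * n))]
  if (length(discarded)) {
    message(length(discarded), " majority ids discarded by equalized down-sampling")
  }
  out <- lapply(seq_len(k), function(i) {
    c(used[((i - 1) * n + 1):(i * n)], minority_ids)
  })
  attr(out, "discarded") <- discarded
  out
}

# ---- base learners ----------------------------------------------------

.beed_base_kinds <- c("LDA", "RF", "NN", "AdaBoost", "XGBoost", "SVM")

fit_base_learner <- function(kind, x, y01) {
  x <- as.matrix(x)
  yf <- factor(y01, levels = c(0, 1))
  fit <- switch(kind,
    LDA = MASS::lda(x, grouping = yf),
    RF = randomForest::randomForest(x, yf, ntree = 300),
    NN = nnet::nnet(x, as.numeric(y01), size = 5, decay = 0.1,
                    maxit = 300, trace = FALSE),
    AdaBoost = fit_adaboost_stumps(x, y01),
    XGBoost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y01, nthread = 1),
      nrounds = 50, verbose = 0),
    SVM = e1071::svm(x, yf, probability = TRUE),
    stop("unknown base kind: ", kind, call. = FALSE)
  )
  structure(list(kind = kind, fit = fit, features = colnames(x)),
            class = "beed_member_fit")
}

# probability of the positive class
score_base_learner <- function(member, x) {
  x <- as.matrix(x)[, member$features, drop = FALSE]
  switch(member$kind,
    LDA = as.numeric(stats::predict(member$fit, x)$posterior[, "1"]),
    RF = as.numeric(stats::predict(member$fit, x, type = "prob")[, "1"]),
    NN = as.numeric(stats::predict(member$fit, x)),
    AdaBoost = predict_adaboost_stumps(member$fit, x),
    XGBoost = as.numeric(stats::predict(member$fit,
                                        xgboost::xgb.DMatrix(x, nthread = 1))),
    SVM = {
      p <- stats::predict(member$fit, x, probability = TRUE)
      as.numeric(attr(p, "probabilities")[, "1"])
    }
  )
}

# compact discrete AdaBoost over decision stumps
fit_adaboost_stumps <- function(x, y01, rounds = 50) {
  n <- nrow(x)
  yy <- ifelse(y01 == 1, 1, -1)
  w <- rep(1 / n, n)
  df <- data.frame(x, .y = factor(y01, levels = c(0, 1)))
  ctl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, cp = -1, xval = 0)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    st <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = ctl)
    h <- ifelse(stats::predict(st, df, type = "class") == "1", 1, -1)
    err <- sum(w[h != yy])
    if (err >= 0.5 && length(stumps)) break
    err <- min(max(err, 1e-10), 0.5 - 1e-10)
    a <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, a)
    w <- w * exp(-a * yy * h)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost_stumps <- function(model, x) {
  df <- data.frame(x)
  f <- rep(0, nrow(df))
  for (i in seq_along(model$stumps)) {
    h <- ifelse(stats::predict(model$stumps[[i]], df, type = "class") == "1", 1, -1)
    f <- f + model$alphas[i] * h
  }
  (f / sum(model$alphas) + 1) / 2
}

# ---- ensemble ---------------------------------------------------------

#' Cross-subset AUC of each ensemble member
#'
#' Member i is scored on the union of all subsets other than its own,
#' deduplicated by id (the minority rows are shared by every subset).
#'
#' @param members list of fitted members (internal fit objects).
#' @param subsets list of id vectors as produced by
#'   [equalized_downsample()].
#' @param table the training table (with `id`, `label`, features).
#' @return numeric AUC per member.
#' @export
member_aucs <- function(members, subsets, table) {
  stopifnot(length(members) == length(subsets), length(members) >= 2)
  vapply(seq_along(members), function(i) {
    ids <- unique(unlist(subsets[-i]))
    rows <- table[match(ids, table$id), ]
    if (length(unique(rows$label)) < 2) {
      stop("cross-subset evaluation set is single-class", call. = FALSE)
    }
    sc <- score_base_learner(members[[i]],
                             as.matrix(rows[, members[[i]]$features]))
    auc_score(rows$label, sc)
  }, numeric(1))
}

#' Min-max normalised member weights
#'
#' `w_i = (auc_i - min) / (max - min)`; when all AUCs are equal every
#' weight is 1.
#'
#' @param aucs numeric vector of member AUCs.
#' @return weights in `[0, 1]`.
#' @examples
#' compute_weights(c(0.6, 0.7, 0.8))  # 0, 0.5, 1
#' @export
compute_weights <- function(aucs) {
  stopifnot(length(aucs) >= 1)
  rng <- range(aucs)
  if (diff(rng) == 0) return(rep(1, length(aucs)))
  (aucs - rng[1]) / diff(rng)
}

#' Train a BEED ensemble
#'
#' Ranks features on the training table, keeps the top `k`, builds the
#' balanced subsets, fits one base classifier per subset, and attaches
#' cross-subset AUCs and min-max weights.
#'
#' @param table data frame with a 0/1 `label` column (1 = invasive =
#'   positive), optional `id` column, and numeric features.
#' @param base_kind one of `"LDA"`, `"RF"`, `"NN"`, `"AdaBoost"`,
#'   `"XGBoost"`, `"SVM"`.
#' @param feature_method ranker passed to [rank_features()], or `"none"`
#'   to keep all features.
#' @param k number of features to keep (default: all).
#' @param criterion decision threshold on the combined vote, default 0.5.
#' @param seed integer seed controlling the subset shuffle and any
#'   stochastic base learner.
#' @return an object of class `beed_model`.
#' @export
train_beed <- function(table, base_kind = "RF", feature_method = "info_gain",
                       k = NULL, criterion = 0.5, seed = 1L) {
  base_kind <- match.arg(base_kind, .beed_base_kinds)
  stopifnot(is.data.frame(table), "label" %in% names(table))
  table <- tibble::as_tibble(table)
  if (!"id" %in% names(table)) table$id <- seq_len(nrow(table))
  lab <- as_binary_label(table$label)

  if (identical(feature_method, "none")) {
    feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                     c("label", "id"))
    ranks <- NULL
  } else {
    ranks <- rank_features(table[, setdiff(names(table), "id")], feature_method)
    feats <- select_top_k(ranks, k %||% nrow(ranks))
  }

  counts <- table(lab)
  majority_label <- as.integer(names(counts)[which.max(counts)])
  subsets <- equalized_downsample(table$id[lab == majority_label],
                                  table$id[lab != majority_label],
                                  seed = seed)

  members <- withr::with_seed(seed, lapply(subsets, function(ids) {
    rows <- table[match(ids, table$id), ]
    fit_base_learner(base_kind, as.matrix(rows[, feats]),
                     as_binary_label(rows$label))
  }))

  if (length(members) >= 2) {
    aucs <- member_aucs(members, subsets, table)
  } else {
    aucs <- NA_real_
  }
  weights <- if (length(members) >= 2) compute_weights(aucs) else 1

  structure(
    list(members = members, subsets = subsets, aucs = aucs,
         weights = weights, criterion = criterion, features = feats,
         base_kind = base_kind, feature_method = feature_method,
         ranks = ranks, seed = seed,
         discarded = attr(subsets, "discarded")),
    class = "beed_model"
  )
}

#' @export
print.beed_model <- function(x, ...) {
  cat(sprintf("<beed_model> %d x %s member(s), %d feature(s), criterion %g\n",
              length(x$members), x$base_kind, length(x$features), x$criterion))
  if (!anyNA(x$aucs)) {
    cat("  member AUCs:", paste(signif(x$aucs, 3), collapse = " "),
        "| weights:", paste(signif(x$weights, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' Predict with a BEED ensemble
#'
#' Each member casts a hard vote (its own positive-probability > 0.5);
#' votes are combined as `sum(w_i * vote_i) / sum(w_i)` (plain majority
#' when all weights are zero) and the case is positive when the combined
#' score strictly exceeds the criterion.
#'
#' @param object a `beed_model`.
#' @param new_data data frame containing the model's feature columns.
#' @param ... unused.
#' @return tibble with `.score` (combined weighted vote in `[0, 1]`) and
#'   `.label` (0/1).
#' @export
predict.beed_model <- function(object, new_data, ...) {
  missing <- setdiff(object$features, names(new_data))
  if (length(missing)) {
    stop("new_data lacks feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(new_data[, object$features, drop = FALSE])
  votes <- vapply(object$members,
                  function(m) as.numeric(score_base_learner(m, x) > 0.5),
                  numeric(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  combine_votes(votes, object$weights, object$criterion)
}

# weighted-vote combination: rows = cases, cols = member hard votes in {0,1}
combine_votes <- function(votes, weights, criterion = 0.5) {
  stopifnot(ncol(votes) == length(weights))
  score <- if (sum(weights) == 0) rowMeans(votes) else
    as.numeric(votes %*% weights) / sum(weights)
  tibble::tibble(.score = score, .label = as.integer(score > criterion))
}

#' Save / load a BEED model
#'
#' The model is written as a directory: `meta.json` (weights, AUCs,
#' criterion, seed, features, base kind) plus one serialized fit per
#' member.
#'
#' @param model a `beed_model`.
#' @param dir directory path.
#' @return `read_beed()` returns the model; `write_beed()` the path.
#' @export
write_beed <- function(model, dir) {
  stopifnot(inherits(model, "beed_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(base_kind = model$base_kind, criterion = model$criterion,
         seed = model$seed, features = model$features,
         aucs = model$aucs, weights = model$weights,
         feature_method = model$feature_method,
         n_members = length(model$members)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA, na = "null")
  for (i in seq_along(model$members)) {
    saveRDS(model$members[[i]], file.path(dir, sprintf("member_%02d.rds", i)))
  }
  invisible(dir)
}

#' @rdname write_beed
#' @export
read_beed <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  members <- lapply(seq_len(meta$n_members), function(i) {
    readRDS(file.path(dir, sprintf("member_%02d.rds", i)))
  })
  structure(
    list(members = members, subsets = NULL,
         aucs = meta$aucs, weights = meta$weights,
         criterion = meta$criterion, features = meta$features,
         base_kind = meta$base_kind, feature_method = meta$feature_method,
         ranks = NULL, seed = meta$seed, discarded = NULL),
    class = "beed_model"
  )
}
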