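# Wrapper fitness machinery. Two integration strategies over a bank of
# classifiers: "blocking" averages each member's balanced accuracy, so a
# subset must satisfy the whole ensemble rather than one inductive bias;
# "majority voting" scores the consensus prediction. The genetic fitness is
# their weighted sum.

new_classifier <- function(name, fit_predict) {
  structure(list(name = name, fit_predict = fit_predict),
            class = "mfge_classifier")
}

clf_decision_tree <- function() {
  new_classifier("DT", function(x, y, xt) {
    df <- data.frame(x, check.names = FALSE)
    df$.class <- y
    # C4.5-like splitting: rpart's default minsplit of 20 would leave the
    # tree at its root on few-dozen-sample microarray folds
    fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          xval = 0, minsplit = 4, minbucket = 2,
                          maxcompete = 0, maxsurrogate = 0,
                          usesurrogate = 0))
    predict(fit, data.frame(xt, check.names = FALSE), type = "class")
  })
}

clf_random_forest <- function(ntree = 7) {
  new_classifier("RF", function(x, y, xt) {
    fit <- randomForest::randomForest(x, y, ntree = ntree)
    predict(fit, xt)
  })
}

clf_knn <- function(k) {
  new_classifier(paste0(k, "NN"), function(x, y, xt) {
    class::knn(x, xt, y, k = min(k, nrow(x)), use.all = TRUE)
  })
}

clf_naive_bayes <- function() {
  new_classifier("NB", function(x, y, xt) {
    fit <- e1071::naiveBayes(x, y)
    predict(fit, xt)
  })
}

#' Names of the built-in classifiers
#' @return Character vector.
#' @export
classifier_names <- function() c("dt", "rf", "3nn", "7nn", "nb")

#' Assemble a classifier bank
#'
#' The default bank is the five-member ensemble: a decision tree, a random
#' forest of 7 trees, 3- and 7-nearest-neighbour classifiers (Euclidean
#' distance), and Gaussian naive Bayes. Each member is re-fit from scratch
#' for every evaluated subset; any stochastic member (the forest) draws from
#' a seed derived from the bank seed, so evaluation is deterministic.
#'
#' @param members Character vector from [classifier_names()], in voting
#'   order.
#' @param seed Integer bank seed.
#' @param vote_k Number of leading members that take part in the majority
#'   vote; default all of them.
#' @return Object of class `classifier_bank`.
#' @export
classifier_bank <- function(members = classifier_names(), seed = 1,
                            vote_k = length(members)) {
  if (length(members) < 1) stop("bank needs at least one classifier")
  unknown <- setdiff(members, classifier_names())
  if (length(unknown) > 0) {
    stop("unknown classifier(s): ", paste(unknown, collapse = ", "))
  }
  if (vote_k < 1 || vote_k > length(members)) {
    stop("vote_k must be in 1..", length(members))
  }
  builders <- list(
    dt = clf_decision_tree(), rf = clf_random_forest(7),
    `3nn` = clf_knn(3), `7nn` = clf_knn(7), nb = clf_naive_bayes()
  )
  chosen <- builders[members]
  structure(list(members = chosen,
                 names = unname(vapply(chosen, `[[`, character(1),
                                       "name")),
                 seed = seed, vote_k = vote_k, L = length(members)),
            class = "classifier_bank")
}

#' Balanced classification accuracy
#'
#' Mean per-class sensitivity `BC = (1/m) sum_j Se_j`, where `Se_j` is the
#' fraction of class-j samples predicted correctly and `m` is the number of
#' classes in `class_set`. Robust to class imbalance: an all-majority
#' predictor on binary data scores 0.5, not the majority prevalence. A class
#' absent from `actual` contributes sensitivity 0 (with a warning), so
#' degenerate folds penalize rather than inflate the score.
#'
#' @param predicted Predicted class per sample.
#' @param actual True class per sample.
#' @param class_set All `m` class labels; defaults to the levels of
#'   `actual`.
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy <- function(predicted, actual,
                              class_set = levels(as.factor(actual))) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  if (!all(actual %in% class_set)) stop("actual contains unknown classes")
  sens <- vapply(class_set, function(cl) {
    idx <- actual == cl
    if (!any(idx)) {
      warning("class '", cl, "' absent from actual; sensitivity 0")
      return(0)
    }
    mean(predicted[idx] == cl)
  }, numeric(1))
  mean(sens)
}

#' Majority vote over classifier predictions
#'
#' Per sample, the modal class among the first `k` voters. A tie among
#' modal classes goes to the earliest classifier in bank order whose
#' prediction belongs to the tied set, which keeps voting deterministic.
#'
#' @param hypotheses List of equal-length prediction vectors, in bank order.
#' @param k Number of leading voters to use (default all).
#' @return Character vector of voted classes.
#' @export
majority_vote <- function(hypotheses, k = length(hypotheses)) {
  if (k < 1) stop("k must be >= 1")
  if (k > length(hypotheses)) stop("k exceeds number of hypotheses")
  votes <- vapply(hypotheses[seq_len(k)], as.character,
                  character(length(hypotheses[[1]])))
  votes <- matrix(votes, ncol = k)
  apply(votes, 1, function(v) {
    tab <- table(v)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1) return(winners)
    v[v %in% winners][1] # earliest voter among the tied classes
  })
}

#' Evaluate one gene subset's ensemble fitness
#'
#' Fits every bank member on the training slice restricted to `subset` and
#' predicts the test slice. Returns the blocking term (mean balanced
#' accuracy over members), the voting term (balanced accuracy of the
#' majority vote over the bank's first `vote_k` members), and the combined
#' fitness `w1 * blocking + w2 * voting`.
#'
#' @param subset Gene ids or indices; an empty subset scores 0 with a
#'   warning (nothing is fitted).
#' @param train,test `expression_dataset` slices sharing gene universe and
#'   class set.
#' @param bank A [classifier_bank()].
#' @param w1,w2 Contribution weights of blocking and voting (default 0.5
#'   each).
#' @return Object of class `fitness_value`: list with `blocking`, `voting`,
#'   `combined`, and `per_classifier` (named balanced accuracies).
#' @export
evaluate_subset <- function(subset, train, test, bank, w1 = 0.5, w2 = 0.5) {
  if (length(subset) == 0) {
    warning("empty subset: fitness 0")
    return(structure(list(blocking = 0, voting = 0, combined = 0,
                          per_classifier = setNames(rep(0, bank$L),
                                                    bank$names)),
                     class = "fitness_value"))
  }
  if (is.character(subset)) subset <- match(subset, train$gene_ids)
  class_set <- levels(train$labels)
  x <- t(train$values[subset, , drop = FALSE])
  xt <- t(test$values[subset, , drop = FALSE])
  colnames(x) <- colnames(xt) <- train$gene_ids[subset]
  y <- factor(train$labels, levels = class_set)
  actual <- as.character(test$labels)

  hyps <- vector("list", bank$L)
  bc <- numeric(bank$L)
  for (i in seq_len(bank$L)) {
    hyps[[i]] <- with_seed(derive_seed(bank$seed, i),
                           bank$members[[i]]$fit_predict(x, y, xt))
    bc[i] <- balanced_accuracy(hyps[[i]], actual, class_set)
  }
  blocking <- mean(bc)
  voting <- balanced_accuracy(majority_vote(hyps, bank$vote_k), actual,
                              class_set)
  structure(list(blocking = blocking, voting = voting,
                 combined = w1 * blocking + w2 * voting,
                 per_classifier = setNames(bc, bank$names)),
            class = "fitness_value")
}

#' @export
print.fitness_value <- function(x, ...) {
  cat(sprintf("fitness: combined %.4f (blocking %.4f, voting %.4f)\n",
              x$combined, x$blocking, x$voting))
  invisible(x)
}
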