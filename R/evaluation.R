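#' Trial definitions for response discrimination
#'
#' The six two-class comparisons used throughout the evaluation, each
#' defined by predicates on the event annotation.  The positive class
#' is the response class (the class a higher discriminant score should
#' predict); the negative class is the no-response class.
#'
#' * `trial1`: sluggish response (RSS = 5) vs no response (RSS = 6)
#' * `trial2`: any response (RSS < 6) vs no response (RSS = 6)
#' * `trial3`: strong response (RSS < 5) vs sluggish (RSS = 5)
#' * `trial4`: strong response (RSS < 5) vs no response (RSS = 6)
#' * `trial5`: strong response (RSS < 5) vs RSS >= 5
#' * `gag`: gag reflex present (GAG = 1) vs absent (GAG = 0)
#'
#' @param name One of `"trial1"` .. `"trial5"`, `"gag"`.
#' @return An object of class `trial_definition` with predicate
#'   functions `positive(kind, value)` and `negative(kind, value)`.
#' @export
trial_definition <- function(name = c("trial1", "trial2", "trial3",
                                      "trial4", "trial5", "gag")) {
  name <- match.arg(name)
  preds <- switch(name,
    trial1 = list(pos = function(k, v) k == "RSS" & v == 5,
                  neg = function(k, v) k == "RSS" & v == 6),
    trial2 = list(pos = function(k, v) k == "RSS" & v < 6,
                  neg = function(k, v) k == "RSS" & v == 6),
    trial3 = list(pos = function(k, v) k == "RSS" & v < 5,
                  neg = function(k, v) k == "RSS" & v == 5),
    trial4 = list(pos = function(k, v) k == "RSS" & v < 5,
                  neg = function(k, v) k == "RSS" & v == 6),
    trial5 = list(pos = function(k, v) k == "RSS" & v < 5,
                  neg = function(k, v) k == "RSS" & v >= 5),
    gag    = list(pos = function(k, v) k == "GAG" & v == 1,
                  neg = function(k, v) k == "GAG" & v == 0))
  structure(list(name = name, positive = preds$pos, negative = preds$neg),
            class = "trial_definition")
}

#' Label a measure table under a trial definition
#'
#' Keeps the rows whose event falls in either class of the trial and
#' attaches a binary label (1 = response).
#'
#' @param measures A feature table from [compute_measures()] (must
#'   carry `event_kind` and `event_value` columns).
#' @param trial A [trial_definition()] or trial name.
#' @return A list of class `labeled_dataset`: `measures` (numeric
#'   measure columns only), `labels` (0/1), `trial`.
#' @export
apply_trial <- function(measures, trial) {
  if (is.character(trial)) trial <- trial_definition(trial)
  k <- measures$event_kind
  v <- measures$event_value
  pos <- trial$positive(k, v)
  neg <- trial$negative(k, v)
  keep <- pos | neg
  if (!any(pos) || !any(neg)) {
    stop("trial ", trial$name, ": one of the classes is empty")
  }
  meta <- c("event_time", "event_kind", "event_value", "n_rejected")
  mcols <- setdiff(names(measures), meta)
  structure(list(measures = measures[keep, mcols, drop = FALSE],
                 labels = as.integer(pos[keep]), trial = trial$name),
            class = "labeled_dataset")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples: exact for small
#' untied samples, tie-corrected normal approximation otherwise
#' (via [stats::wilcox.test()]).  `U` is the number of pairs `(x, y)`
#' with `x > y` (ties counted half).
#'
#' @param x,y Numeric vectors (non-empty).
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Bonferroni correction with an explicit family size
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of comparisons in the family (defaults to
#'   `length(p)`).
#' @return Adjusted p-values `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Prediction probability Pk
#'
#' Probability that the indicator correctly orders a randomly drawn
#' between-class pair, with score ties counted half: over all pairs of
#' one response (label 1) and one no-response (label 0) window,
#' `Pk = (concordant + 0.5 * tied) / n_pairs`, where a pair is
#' concordant when the response window has the higher score.  0.5 is
#' chance, 1 is perfect.  The standard error is the delete-one
#' jackknife over windows.
#'
#' @param scores Numeric predictor values.
#' @param labels Binary labels (1 = response).
#' @param se Compute the jackknife standard error (default TRUE).
#' @return List with `pk`, `se_pk`, `n` (number of windows).
#' @export
pk_statistic <- function(scores, labels, se = TRUE) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both classes must be present")
  }
  pk <- .pk_value(scores, labels)
  se_pk <- NA_real_
  if (se) {
    n <- length(scores)
    jk <- vapply(seq_len(n), function(i) {
      li <- labels[-i]
      if (!any(li == 1) || !any(li == 0)) return(pk)
      .pk_value(scores[-i], li)
    }, numeric(1))
    se_pk <- sqrt((n - 1) / n * sum((jk - mean(jk))^2))
  }
  list(pk = pk, se_pk = se_pk, n = length(scores))
}

# rank-based Pk: equals brute-force pair counting with half ties
.pk_value <- function(scores, labels) {
  r <- rank(scores)                    # midranks handle score ties
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare two Pk values
#'
#' Two-sided test of the difference of two prediction probabilities
#' using their standard errors: the statistic
#' `(pk_a - pk_b) / sqrt(se_a^2 + se_b^2)` is referred to the standard
#' normal distribution.
#'
#' @param a,b Results carrying `pk` and `se_pk` (e.g. from
#'   [pk_statistic()] or [loo_evaluate()]).
#' @return Two-sided p-value.
#' @export
compare_pk <- function(a, b) {
  se <- sqrt(a$se_pk^2 + b$se_pk^2)
  if (!is.finite(se) || se == 0) {
    if (a$pk == b$pk) return(1)
    stop("zero combined standard error")
  }
  z <- (a$pk - b$pk) / se
  2 * stats::pnorm(-abs(z))
}

#' Fit a linear discriminant
#'
#' Linear discriminant with pooled within-class covariance and equal
#' priors: weights `w = S^-1 (mu1 - mu0)`, decision threshold at the
#' midpoint of the projected class means.  Scores are oriented so that
#' the response class (label 1) projects higher.
#'
#' @param measures Numeric matrix or data frame (windows x measures).
#' @param labels Binary labels (1 = response), >= 2 windows per class.
#' @return An object of class `discriminant_model` with `weights`,
#'   `threshold`, `means`, `pooled_cov`.
#' @export
fit_discriminant <- function(measures, labels) {
  X <- as.matrix(measures)
  labels <- as.integer(labels)
  if (sum(labels == 1) < 2L || sum(labels == 0) < 2L) {
    stop("need at least 2 windows per class")
  }
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("constant measure in the training data")
  }
  X1 <- X[labels == 1, , drop = FALSE]
  X0 <- X[labels == 0, , drop = FALSE]
  mu1 <- colMeans(X1); mu0 <- colMeans(X0)
  n1 <- nrow(X1); n0 <- nrow(X0)
  Sp <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X0, 2, mu0))) /
    (n1 + n0 - 2)
  w <- tryCatch(solve(Sp, mu1 - mu0),
                error = function(e) stop(
                  "singular pooled covariance: reduce the measure subset",
                  call. = FALSE))
  structure(list(weights = w, threshold = sum(w * (mu1 + mu0)) / 2,
                 means = rbind(`0` = mu0, `1` = mu1), pooled_cov = Sp),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model: %d measure(s), threshold %.4g>\n",
              length(x$weights), x$threshold))
  invisible(x)
}

#' Discriminant scores and classes for new windows
#'
#' @param object A [fit_discriminant()] model.
#' @param newdata Matrix or data frame with the model's measures.
#' @param ... Unused.
#' @return Data frame with `score` (signed distance from the
#'   threshold; positive predicts response) and `class` (0/1).
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  s <- drop(X %*% object$weights) - object$threshold
  data.frame(score = s, class = as.integer(s > 0))
}

#' Leave-one-out evaluation of a measure subset
#'
#' For each window, a discriminant is fitted on all other windows and
#' the held-out window is scored and classified.  Sensitivity is the
#' percentage of response windows classified as response; specificity
#' the percentage of no-response windows classified as no-response;
#' Pk (with jackknife SE) is computed on the held-out scores.
#'
#' @param dataset A `labeled_dataset` from [apply_trial()], or a list
#'   with `measures` and `labels`.
#' @param subset Character vector of measure names to use (default all).
#' @return An object of class `eval_result`: `pk`, `se_pk`, `sen`,
#'   `spe` (percent), `subset`, `n`, and the per-window `predictions`
#'   log (scores + classes), from which the confusion counts are
#'   recomputable.
#' @export
loo_evaluate <- function(dataset, subset = NULL) {
  X <- as.matrix(dataset$measures)
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(X))
    if (length(missing)) stop("unknown measure(s): ",
                              paste(missing, collapse = ", "))
    X <- X[, subset, drop = FALSE]
  }
  labels <- as.integer(dataset$labels)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  labels <- labels[ok]
  n <- nrow(X)
  if (sum(labels == 1) < 3L || sum(labels == 0) < 3L) {
    stop("need at least 3 windows per class for leave-one-out")
  }
  scores <- numeric(n)
  classes <- integer(n)
  for (i in seq_len(n)) {
    fit <- fit_discriminant(X[-i, , drop = FALSE], labels[-i])
    pr <- predict(fit, X[i, , drop = FALSE])
    scores[i] <- pr$score
    classes[i] <- pr$class
  }
  sen <- 100 * mean(classes[labels == 1] == 1)
  spe <- 100 * mean(classes[labels == 0] == 0)
  pk <- pk_statistic(scores, labels)
  structure(list(pk = pk$pk, se_pk = pk$se_pk, sen = sen, spe = spe,
                 subset = colnames(X), n = n,
                 predictions = data.frame(score = scores, class = classes,
                                          label = labels)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result [%s]: Pk %.4f (SE %.4f), Sen %.1f%%, Spe %.1f%%, n=%d>\n",
    paste(x$subset, collapse = ", "), x$pk, x$se_pk, x$sen, x$spe, x$n))
  invisible(x)
}

#' Screen measures across trials
#'
#' Mann-Whitney comparison of every measure between the two classes of
#' each trial, Bonferroni-corrected within trial by the number of
#' measures tested.  The candidate pool for the subset search is every
#' measure significant in at least one trial.
#'
#' @param measures Feature table from [compute_measures()].
#' @param trials Character vector of trial names to screen over.
#' @param alpha Significance level on the corrected p-values.
#' @return List with `table` (measure x trial corrected p-values) and
#'   `candidates` (measure names significant in >= 1 trial).
#' @export
screen_measures <- function(measures, trials = c("trial1", "trial2",
                                                 "trial3", "trial4",
                                                 "trial5"),
                            alpha = 0.05) {
  meta <- c("event_time", "event_kind", "event_value", "n_rejected")
  mcols <- setdiff(names(measures), meta)
  tab <- matrix(NA_real_, nrow = length(mcols), ncol = length(trials),
                dimnames = list(mcols, trials))
  for (tr in trials) {
    ds <- tryCatch(apply_trial(measures, tr), error = function(e) NULL)
    if (is.null(ds)) next
    p_raw <- vapply(mcols, function(mc) {
      x <- ds$measures[[mc]][ds$labels == 1]
      y <- ds$measures[[mc]][ds$labels == 0]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (!length(x) || !length(y)) return(NA_real_)
      mann_whitney(x, y)$p
    }, numeric(1))
    tab[, tr] <- bonferroni(p_raw, m = length(mcols))
  }
  sig <- apply(tab, 1, function(p) any(p < alpha, na.rm = TRUE))
  list(table = tab, candidates = mcols[sig])
}

#' Randomized constrained feature-subset search
#'
#' Each iteration draws up to `max_size` measures from the candidate
#' pool whose pairwise absolute rank correlations stay below
#' `corr_threshold`, evaluates the subset by leave-one-out discriminant
#' classification, and keeps it when both sensitivity and specificity
#' exceed their floors.  Results are ranked by Pk (ties broken by
#' higher Sen + Spe, then lexicographic subset name), and the whole
#' search is reproducible given `seed`.
#'
#' @param dataset A `labeled_dataset` from [apply_trial()].
#' @param candidates Character vector: the candidate measure pool
#'   (typically [screen_measures()]` $candidates`).
#' @param max_size Maximum subset size, default 4.
#' @param corr_threshold Maximum absolute Spearman correlation allowed
#'   within a subset, default 0.7.
#' @param n_iter Number of random draws, default 1000.
#' @param min_sen,min_spe Constraint floors in percent, default 60.
#' @param seed Integer seed for the draw sequence.
#' @return A data frame ranked by Pk (columns `subset`, `pk`, `se_pk`,
#'   `sen`, `spe`), possibly with zero rows when no subset meets the
#'   constraints.
#' @export
random_subset_search <- function(dataset, candidates, max_size = 4L,
                                 corr_threshold = 0.7, n_iter = 1000L,
                                 min_sen = 60, min_spe = 60, seed = 1L) {
  if (!length(candidates)) stop("empty candidate pool")
  X <- as.matrix(dataset$measures[, candidates, drop = FALSE])
  ok <- stats::complete.cases(X)
  Xc <- X[ok, , drop = FALSE]
  rho <- stats::cor(Xc, method = "spearman")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  seen <- new.env(parent = emptyenv())
  res <- list()
  for (it in seq_len(n_iter)) {
    perm <- sample(candidates)
    sel <- perm[1]
    for (cand in perm[-1]) {
      if (length(sel) >= max_size) break
      if (all(abs(rho[cand, sel]) < corr_threshold)) sel <- c(sel, cand)
    }
    key <- paste(sort(sel), collapse = "|")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    ev <- tryCatch(loo_evaluate(dataset, sel), error = function(e) NULL)
    if (is.null(ev)) next
    if (ev$sen > min_sen && ev$spe > min_spe) {
      res[[length(res) + 1L]] <- data.frame(
        subset = key, pk = ev$pk, se_pk = ev$se_pk, sen = ev$sen,
        spe = ev$spe)
    }
  }
  if (!length(res)) {
    return(data.frame(subset = character(), pk = numeric(),
                      se_pk = numeric(), sen = numeric(),
                      spe = numeric()))
  }
  out <- do.call(rbind, res)
  ord <- order(-out$pk, -(out$sen + out$spe), out$subset)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, globalenv())
}
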