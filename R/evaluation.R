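# Evaluation: sensor performance index, trajectory agreement metrics,
# repetition-blocked cross-validation, ANOVA modality comparison, and
# results aggregation.

#' Construct a sensor benchmark quadruple
#'
#' @param s_gesture_mean mean signal during gesture (a.u.).
#' @param s_rest_mean mean signal during rest (a.u.).
#' @param luminosity LED luminous intensity (datasheet units), > 0.
#' @param responsivity photodiode responsivity at the LED's dominant
#'   wavelength (datasheet units), > 0.
#' @return a [SensorBench-class]
#' @export
sensorBench <- function(s_gesture_mean, s_rest_mean, luminosity,
                        responsivity) {
  if (luminosity * responsivity == 0) {
    stop_domain("luminosity * responsivity must be non-zero")
  }
  new("SensorBench", sGestureMean = s_gesture_mean, sRestMean = s_rest_mean,
      luminosity = luminosity, responsivity = responsivity)
}

#' Sensor performance index
#'
#' The figure of merit `I = |mean(S_gesture) - mean(S_rest)| / (Phi_v * R_p)`:
#' the rest-to-gesture signal deflection normalized by LED luminous intensity
#' and photodiode responsivity, making modules with different LEDs and
#' detector sensitivities comparable.
#'
#' @param b a [SensorBench-class].
#' @return unitless index value.
#' @examples
#' performanceIndex(sensorBench(2, 1, 4, 0.5))  # 0.5
#' @export
performanceIndex <- function(b) {
  validObject(b)
  abs(b@sGestureMean - b@sRestMean) / (b@luminosity * b@responsivity)
}

#' Normalized mean square error fit score (percent)
#'
#' `NMSE(%) = 100 * (1 - ||x_ref - x_pred||^2 / ||x_ref - mean(x_ref)||^2)`.
#' 100 iff the trajectories are identical; 0 when the prediction is no better
#' than the reference mean; negative when it is worse.
#'
#' @param x_ref reference trajectory (must be non-constant).
#' @param x_pred predicted trajectory of the same length.
#' @return NMSE in percent.
#' @export
nmsePercent <- function(x_ref, x_pred) {
  if (length(x_ref) != length(x_pred)) {
    stop_contract("trajectories must have equal length")
  }
  den <- sum((x_ref - mean(x_ref))^2)
  if (den == 0) stop_domain("reference trajectory is constant (zero denominator)")
  100 * (1 - sum((x_ref - x_pred)^2) / den)
}

#' Pearson correlation coefficient
#'
#' @param x,y equal-length numeric series of length >= 2, both non-constant.
#' @return correlation in \[-1, 1\].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_contract("series must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

#' One-way ANOVA of two groups
#'
#' Classical (equal-variance) one-way ANOVA F statistic and p-value, as used
#' to compare the accuracies of the models trained on the two sensing
#' modalities. Degenerate input with zero variance everywhere and equal
#' means returns `F = 0, p = 1` by convention.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `F`, `p`, `df` (numerator, denominator).
#' @export
anovaOneWay <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_contract("each group needs at least 2 values")
  }
  values <- c(group_a, group_b)
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  ssw <- sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)
  df <- c(1L, length(values) - 2L)
  if (ssw == 0) {
    if (mean(group_a) == mean(group_b)) return(list(F = 0, p = 1, df = df))
    return(list(F = Inf, p = 0, df = df))
  }
  ht <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value), df = df)
}

# Partition repetition ids into k nearly equal groups (seeded shuffle);
# fold sizes differ by at most one repetition.
partition_repetitions <- function(reps, k, seed) {
  u <- sort(unique(reps))
  if (length(u) < k) {
    stop_config(sprintf("%d repetitions cannot form %d repetition-blocked folds",
                        length(u), k))
  }
  ushuf <- with_seed(seed, sample(u))
  split(ushuf, rep(seq_len(k), length.out = length(ushuf)))
}

default_trainer <- function(spec, cfg) {
  function(xtrain, ytrain) {
    fitted <- trainDecoder(spec, xtrain, ytrain, cfg)
    function(xtest) {
      pr <- predictDecoder(fitted, xtest)
      if (spec@task == "classification") pr$labels else pr
    }
  }
}

subset_input <- function(x, idx) {
  if (is(x, "WindowSet")) return(subsetWindows(x, idx))
  if (is(x, "FeatureTable")) {
    return(new("FeatureTable", values = x@values[idx, , drop = FALSE],
               thresholds = x@thresholds, labels = x@labels[idx],
               repetitionIds = x@repetitionIds[idx]))
  }
  stop_contract("cross-validation input must be a WindowSet or FeatureTable")
}

#' Repetition-blocked k-fold cross-validated classification
#'
#' Folds partition whole movement repetitions (default) so that 90%
#' overlapping windows never straddle train and test; `"window-random"`
#' grouping (folds over windows, closer to a record-level split and
#' optimistic under window overlap) is available. Per-fold accuracy is
#' correct/total on the held-out windows. A leakage guard asserts train/test
#' repetition disjointness on every fold.
#'
#' @param x a [WindowSet-class] (raw windows) or [FeatureTable-class].
#' @param spec a [ModelSpec-class] with `task = "classification"`.
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @param cfg a [TrainConfig-class].
#' @param grouping `"repetition-blocked"` or `"window-random"`.
#' @param trainer optional `function(xtrain, ytrain) -> function(xtest)`
#'   overriding the decoder (used for oracle/stub evaluation).
#' @return a [CVReport-class] with per-fold `accuracy`.
#' @export
crossvalClassification <- function(x, spec = NULL, k = 5, seed = 1,
                                   cfg = trainConfig(),
                                   grouping = c("repetition-blocked",
                                                "window-random"),
                                   trainer = NULL) {
  grouping <- match.arg(grouping)
  k <- as.integer(k)
  if (k < 2L) stop_config("k must be >= 2")
  labels <- windowLabels(x)
  reps <- windowRepetitions(x)
  N <- length(labels)
  trainer <- trainer %||% default_trainer(spec, cfg)

  if (grouping == "repetition-blocked") {
    folds <- partition_repetitions(reps, k, seed)
    test_sets <- lapply(folds, function(f) which(reps %in% f))
  } else {
    idx <- with_seed(seed, sample.int(N))
    test_sets <- split(idx, rep(seq_len(k), length.out = N))
  }
  acc <- numeric(k)
  for (i in seq_len(k)) {
    test <- sort(test_sets[[i]])
    train <- setdiff(seq_len(N), test)
    if (!length(test)) stop_config(sprintf("fold %d has an empty test set", i))
    if (grouping == "repetition-blocked" &&
        length(intersect(reps[train], reps[test]))) {
      stop_contract("leakage: a repetition appears in both train and test")
    }
    predict_fun <- trainer(subset_input(x, train), labels[train])
    pred <- predict_fun(subset_input(x, test))
    acc[i] <- mean(pred == labels[test])
  }
  per_fold <- data.frame(fold = seq_len(k), accuracy = acc)
  new("CVReport", perFold = per_fold,
      means = c(accuracy = mean(acc)), stds = c(accuracy = stats::sd(acc)),
      k = k, grouping = grouping, metricNames = "accuracy",
      leakageChecked = grouping == "repetition-blocked")
}

#' Leave-one-repetition-out cross-validated force regression
#'
#' Requires exactly `folds` repetitions; fold i trains on all other
#' repetitions and tests on repetition i only. Input windows should already
#' be restricted to force-active periods. Per-fold metrics are the Pearson
#' correlation and the NMSE fit score between the predicted and true force
#' trajectories, concatenated over the held-out repetition's windows in time
#' order.
#'
#' @param ws a [WindowSet-class] with per-window `targets`.
#' @param spec a [ModelSpec-class] with `task = "regression"`.
#' @param folds number of folds (= number of repetitions).
#' @param cfg a [TrainConfig-class].
#' @param trainer optional trainer override (see
#'   [crossvalClassification()]).
#' @return a [CVReport-class] with per-fold `pearson` and `nmse`.
#' @export
crossvalRegression <- function(ws, spec = NULL, folds = 10,
                               cfg = trainConfig(loss = "MSE"),
                               trainer = NULL) {
  folds <- as.integer(folds)
  reps <- windowRepetitions(ws)
  u <- sort(unique(reps))
  if (length(u) != folds) {
    stop_config(sprintf("found %d repetitions but %d folds requested; need one repetition per fold",
                        length(u), folds))
  }
  targets <- windowTargets(ws)
  if (!length(targets)) stop_contract("window set carries no force targets")
  trainer <- trainer %||% default_trainer(spec, cfg)
  pearson <- numeric(folds)
  nmse <- numeric(folds)
  for (i in seq_len(folds)) {
    test <- which(reps == u[i])
    train <- which(reps != u[i])
    if (length(intersect(reps[train], reps[test]))) {
      stop_contract("leakage: a repetition appears in both train and test")
    }
    predict_fun <- trainer(subsetWindows(ws, train), targets[train])
    pred <- predict_fun(subsetWindows(ws, test))
    truth <- targets[test]
    # a degenerate (constant) prediction has no defined correlation but
    # still has an NMSE fit score
    pearson[i] <- if (stats::sd(pred) == 0 || stats::sd(truth) == 0)
      NA_real_ else pearsonR(truth, pred)
    nmse[i] <- nmsePercent(truth, pred)
  }
  per_fold <- data.frame(fold = seq_len(folds), pearson = pearson,
                         nmse = nmse)
  new("CVReport", perFold = per_fold,
      means = c(pearson = mean(pearson), nmse = mean(nmse)),
      stds = c(pearson = stats::sd(pearson), nmse = stats::sd(nmse)),
      k = folds, grouping = "repetition-blocked",
      metricNames = c("pearson", "nmse"), leakageChecked = TRUE)
}

#' Aggregate per-subject results into a study-style table
#'
#' Subject rows with metric columns are completed with an `AVG` row (the
#' arithmetic mean of the subject rows), per-column maxima, and — when
#' paired LMG/EMG columns are declared — per-subject flags marking the
#' better-performing modality.
#'
#' @param df data.frame with a `subject` column and numeric metric columns;
#'   one row per subject.
#' @param compare optional named list of `c(lmg_column, emg_column)` pairs;
#'   adds a logical `<name>_lmg_better` flag column per pair.
#' @return a [ResultsTable-class]
#' @export
aggregateResults <- function(df, compare = NULL) {
  if (!"subject" %in% names(df)) stop_config("df needs a 'subject' column")
  metric_cols <- setdiff(names(df), "subject")
  for (mc in metric_cols) {
    if (any(is.na(df[[mc]]))) {
      bad <- df$subject[which(is.na(df[[mc]]))[1]]
      stop_config(sprintf("missing result cell: subject '%s', column '%s'",
                          bad, mc))
    }
  }
  avg <- vapply(df[metric_cols], mean, numeric(1))
  maxima <- vapply(df[metric_cols], max, numeric(1))
  avg_row <- df[1, , drop = FALSE]
  avg_row$subject <- "AVG"
  avg_row[metric_cols] <- as.list(avg)
  tab <- rbind(df, avg_row)
  rownames(tab) <- NULL
  better <- data.frame()
  if (!is.null(compare)) {
    better <- data.frame(subject = df$subject)
    for (nm in names(compare)) {
      pr <- compare[[nm]]
      if (!all(pr %in% metric_cols)) {
        stop_config(sprintf("compare pair '%s' names unknown columns", nm))
      }
      better[[paste0(nm, "_lmg_better")]] <- df[[pr[1]]] > df[[pr[2]]]
    }
  }
  new("ResultsTable", table = tab, maxima = maxima, better = better)
}
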