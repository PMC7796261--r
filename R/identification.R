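#' LSTM classifier configuration
#'
#' Architecture and optimizer settings for the built-in LSTM sequence
#' classifier: up to three recurrent layers of widths `n`, `n/2`, `n/3`
#' (with `n` the samples per beat after resampling to `input_length`), two
#' ReLU dense layers with dropout, and a softmax output sized to the number
#' of enrolled subjects. The optimizer is RMSprop with learning rate 0.001
#' and 10 epochs by default.
#'
#' @param input_length samples per beat fed to the network; beats are
#'   resampled to this length (default 60, kept small so training runs in
#'   seconds on one CPU).
#' @param n_layers number of recurrent layers (1, 2 or 3).
#' @param lstm_widths recurrent widths; default `n, n/2, n/3` truncated to
#'   `n_layers`.
#' @param dense_widths dense-layer widths (default 400, 200; reduce for
#'   small studies).
#' @param dropout dropout rate on the dense layers, in `[0, 1)`.
#' @param learning_rate RMSprop learning rate.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(input_length = 60, n_layers = 3,
                        lstm_widths = NULL, dense_widths = c(400, 200),
                        dropout = 0.5, learning_rate = 0.001, epochs = 10,
                        batch_size = 4, seed = 1L) {
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must lie in [0, 1)", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (!n_layers %in% 1:3) stop("`n_layers` must be 1, 2 or 3", call. = FALSE)
  n <- as.integer(input_length)
  if (is.null(lstm_widths))
    lstm_widths <- pmax(2L, c(n, n %/% 2L, n %/% 3L))[seq_len(n_layers)]
  structure(list(input_length = n, n_layers = n_layers,
                 lstm_widths = as.integer(lstm_widths),
                 dense_widths = as.integer(dense_widths),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "lstm_config")
}

#' Fit a subject-identification model on labeled beats
#'
#' Enrolls subjects from labeled registration beats (acquired at rest) and
#' returns a classifier. Two methods are available: `"nearest"`, a
#' deterministic nearest-template classifier scoring each probe beat by its
#' mean Euclidean distance to every enrolled subject's beats, and
#' `"lstm"`, the built-in LSTM sequence classifier (see [lstm_config]).
#' Both are deterministic under the configured seed.
#'
#' @param cycles list of [ecg_cycle] objects, all of equal length.
#' @param labels subject label per cycle (character or factor); at least
#'   two distinct subjects are required.
#' @param method `"nearest"` or `"lstm"`.
#' @param config an [lstm_config] (used by `method = "lstm"`).
#' @return An object of class `ecg_identifier` with `predict`, `print` and
#'   `summary` methods.
#' @examples
#' \donttest{
#' cohort <- make_cohort(2, seed = 1)
#' recs <- synthesize_cohort_records(cohort, condition = "sit",
#'                                   reg_duration = 20, rec_duration = 10,
#'                                   fs = 250, seed = 1)
#' cyc <- unlist(lapply(recs, function(r) {
#'   pp <- preprocess_record(r$registration)
#'   segment_cycles(pp$record, pp$peaks)
#' }), recursive = FALSE)
#' labs <- vapply(cyc, function(cy) cy$subject_id, character(1))
#' fit <- ecg_identifier(cyc, labs, method = "nearest")
#' fit
#' }
#' @export
ecg_identifier <- function(cycles, labels, method = c("nearest", "lstm"),
                           config = lstm_config()) {
  method <- match.arg(method)
  if (length(cycles) != length(labels))
    stop("`labels` must have one entry per cycle", call. = FALSE)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("degenerate enrollment: at least two subjects are required",
         call. = FALSE)
  if (any(table(labels) < 1L))
    stop("every subject needs at least one cycle", call. = FALSE)
  n_len <- if (method == "lstm") config$input_length else
    length(cycles[[1]]$samples)
  X <- t(vapply(cycles, function(cy)
    match_length(cy, n_len)$samples, numeric(n_len)))
  y <- match(labels, classes)
  fit <- list(method = method, classes = classes, input_length = n_len,
              config = config, n_train = length(cycles))
  if (method == "nearest") {
    fit$templates <- lapply(seq_along(classes), function(k)
      X[y == k, , drop = FALSE])
    fit$scale <- stats::median(stats::dist(X[sample_rows(nrow(X), 50L), ,
                                             drop = FALSE]))
    if (!is.finite(fit$scale) || fit$scale <= 0) fit$scale <- 1
  } else {
    # per-timestep standardization of the beat waveforms (stored with the
    # fit and re-applied to probes)
    mu <- colMeans(X)
    sg <- apply(X, 2, stats::sd)
    sg[sg < 1e-8] <- 1
    fit$center <- mu
    fit$scale_sd <- sg
    X <- sweep(sweep(X, 2, mu), 2, sg, "/")
    tr <- train_lstm(X, y, n_classes = length(classes),
                     lstm_widths = config$lstm_widths,
                     dense_widths = config$dense_widths,
                     dropout = config$dropout, lr = config$learning_rate,
                     epochs = config$epochs, batch_size = config$batch_size,
                     seed = config$seed)
    fit$layers <- tr$layers
    fit$loss <- tr$loss
  }
  class(fit) <- "ecg_identifier"
  fit
}

sample_rows <- function(n, k) {
  if (n <= k) seq_len(n) else round(seq(1, n, length.out = k))
}

#' @export
print.ecg_identifier <- function(x, ...) {
  cat(sprintf("<ecg_identifier> %s classifier, %d subject(s), %d training beat(s), beat length %d\n",
              x$method, length(x$classes), x$n_train, x$input_length))
  invisible(x)
}

#' @export
summary.ecg_identifier <- function(object, ...) {
  print(object)
  cat("  subjects:", paste(object$classes, collapse = ", "), "\n")
  if (object$method == "lstm") {
    cat(sprintf("  LSTM widths: %s; dense: %s; dropout %.2f; lr %g; epochs %d\n",
                paste(object$config$lstm_widths, collapse = "/"),
                paste(object$config$dense_widths, collapse = "/"),
                object$config$dropout, object$config$learning_rate,
                object$config$epochs))
    cat(sprintf("  final training loss: %.4f\n", utils::tail(object$loss, 1)))
  }
  invisible(object)
}

#' Identify the subject of a set of probe beats
#'
#' Scores every probe beat against the enrolled subjects, averages the
#' per-beat class scores (softmax probabilities) over the set, and returns
#' the highest-scoring subject; ties go to the earliest label in sort
#' order. Probe beats are resampled to the training beat length if needed.
#'
#' @param object an [ecg_identifier] fit.
#' @param newdata non-empty list of [ecg_cycle] objects, a `normalized_set`
#'   from [filter_cycles], or a numeric matrix (one beat per row).
#' @param ... unused.
#' @return List with elements `label` (predicted subject), `scores`
#'   (named mean per-class scores, summing to 1) and `per_cycle` (matrix of
#'   per-beat scores).
#' @export
predict.ecg_identifier <- function(object, newdata, ...) {
  if (inherits(newdata, "normalized_set")) {
    if (is.null(newdata$cycles))
      stop("normalized set carries no cycles; call filter_cycles() with `cycles`",
           call. = FALSE)
    newdata <- newdata$cycles
  }
  if (is.matrix(newdata)) {
    X <- newdata
    if (ncol(X) != object$input_length)
      stop("probe beats must match the training beat length", call. = FALSE)
  } else {
    if (length(newdata) < 1L)
      stop("`newdata` must be non-empty", call. = FALSE)
    X <- t(vapply(newdata, function(cy)
      match_length(cy, object$input_length)$samples,
      numeric(object$input_length)))
  }
  if (object$method == "nearest") {
    D <- vapply(object$templates, function(tm) {
      # mean Euclidean distance of each probe row to the subject's beats
      vapply(seq_len(nrow(X)), function(i)
        mean(sqrt(colSums((t(tm) - X[i, ])^2))), numeric(1))
    }, numeric(nrow(X)))
    D <- matrix(D, nrow = nrow(X))
    Z <- -D / object$scale
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
  } else {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale_sd, "/")
    P <- predict_lstm(object$layers, X)
  }
  colnames(P) <- object$classes
  scores <- colMeans(P)
  list(label = object$classes[which.max(scores)], scores = scores,
       per_cycle = P)
}

#' 1:N confusion counts
#'
#' One-vs-rest tally over a set of identification decisions against `N`
#' enrolled subjects: a correct decision contributes one true positive and
#' `N - 1` true negatives; a wrong decision contributes one false positive
#' (the predicted subject), one false negative (the true subject) and
#' `N - 2` true negatives.
#'
#' @param predicted,truth character vectors of predicted and true subject
#'   labels, same length.
#' @param n_classes number of enrolled subjects `N` (>= 2).
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth, n_classes) {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have the same length", call. = FALSE)
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  n_classes <- as.integer(n_classes)
  correct <- sum(predicted == truth)
  wrong <- sum(predicted != truth)
  structure(list(TP = correct,
                 TN = correct * (n_classes - 1L) + wrong * (n_classes - 2L),
                 FP = wrong, FN = wrong),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (accuracy %.4f)\n",
              x$TP, x$TN, x$FP, x$FN, accuracy(x)))
  invisible(x)
}

#' Identification accuracy
#'
#' `(TP + TN) / (TP + FN + FP + TN)` from 1:N confusion counts.
#'
#' @param counts a `confusion_counts` object, or a list/vector with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, tn, fp, fn) < 0))
    stop("counts must be non-negative", call. = FALSE)
  total <- tp + fn + fp + tn
  if (total == 0) stop("all-zero confusion counts", call. = FALSE)
  (tp + tn) / total
}
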