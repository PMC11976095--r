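# Feed-forward neural classifier: 4 input neurons (the extracted feature
# scores, scaled to [0,1] by each scale's maximum), rectified hidden layers,
# softmax over the four difficulty classes. Trained with full-batch Adam on
# cross-entropy, with a held-out validation fraction for early stopping.
# Written against base R linear algebra: the inputs are 4-dimensional and
# the corpora small, so training is a matter of seconds on one CPU thread.

#' Classifier configuration
#'
#' @param hidden_layers Integer vector of hidden-layer widths (>= 1 layer).
#' @param activation Hidden activation; only "relu" is implemented.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before training halts.
#' @param learning_rate Adam step size.
#' @param seed Integer seed; fixes initialization and the validation split,
#'   making training fully reproducible.
#' @param validation_fraction Fraction of the training data held out for
#'   early stopping, in (0, 1).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(hidden_layers = c(16L, 8L),
                              activation = "relu",
                              max_epochs = 800L,
                              early_stop_patience = 50L,
                              learning_rate = 0.01,
                              seed = 1L,
                              validation_fraction = 0.15) {
  stopifnot(
    length(hidden_layers) >= 1L, all(hidden_layers >= 1L),
    identical(activation, "relu"),
    max_epochs >= 1L, early_stop_patience >= 1L, learning_rate > 0,
    validation_fraction > 0, validation_fraction < 1
  )
  structure(
    list(
      hidden_layers = as.integer(hidden_layers), activation = activation,
      max_epochs = as.integer(max_epochs),
      early_stop_patience = as.integer(early_stop_patience),
      learning_rate = learning_rate, seed = as.integer(seed),
      validation_fraction = validation_fraction
    ),
    class = "classifier_config"
  )
}

# run fn() under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.feature_matrix <- function(features) {
  cols <- unname(FEATURE_COLS)
  if (is.data.frame(features)) {
    stopifnot(all(cols %in% names(features)))
    X <- as.matrix(features[, cols])
  } else {
    X <- as.matrix(features)
    if (ncol(X) != 4L) stop("features must have 4 columns", call. = FALSE)
    colnames(X) <- cols
  }
  for (j in seq_len(4L)) {
    v <- X[, j]
    if (any(is.na(v)) || any(v < 1) || any(v > FEATURE_MAX[[cols[j]]])) {
      stop("feature '", cols[j], "' contains scores outside its scale 1..",
           FEATURE_MAX[[cols[j]]], call. = FALSE)
    }
  }
  # scale each ordinal score by its per-feature maximum
  sweep(X, 2L, FEATURE_MAX[cols], "/")
}

.forward <- function(params, X) {
  a <- X
  zs <- list(); as <- list(a)
  L <- length(params$W)
  for (l in seq_len(L)) {
    z <- a %*% params$W[[l]] + matrix(params$b[[l]], nrow(a),
                                      length(params$b[[l]]), byrow = TRUE)
    zs[[l]] <- z
    a <- if (l < L) pmax(z, 0) else {
      # row-wise softmax, shifted for stability
      e <- exp(z - apply(z, 1L, max))
      e / rowSums(e)
    }
    as[[l + 1L]] <- a
  }
  list(prob = a, zs = zs, as = as)
}

.xent <- function(prob, Y) {
  -mean(log(pmax(rowSums(prob * Y), 1e-12)))
}

#' Train the difficulty classifier
#'
#' @param features Feature scores for >= 20 cases (data frame with columns
#'   `angulation`, `root_count`, `root_curvature`, `canal`, or a 4-column
#'   matrix in that order).
#' @param labels Difficulty classes (character or factor, levels D1..D4);
#'   all four classes must be present.
#' @param cfg A [classifier_config()].
#' @return A `molar_net` model: `config`, `weights`, `class_order`
#'   (D1 < D2 < D3 < D4) and `training_history` (tibble of per-epoch train
#'   loss/accuracy and validation loss).
#' @examples
#' combos <- enumerate_combinations()
#' net <- train_classifier(combos[, 1:4], combos$class, classifier_config(seed = 7))
#' predict(net, data.frame(angulation = 1, root_count = 1,
#'                         root_curvature = 1, canal = 1))
#' @export
train_classifier <- function(features, labels, cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  labels <- as.character(labels)
  X <- .feature_matrix(features)
  if (nrow(X) != length(labels)) {
    stop("features and labels differ in length (", nrow(X), " vs ",
         length(labels), ")", call. = FALSE)
  }
  absent <- setdiff(DIFFICULTY_LABELS, unique(labels))
  if (length(absent) > 0L) {
    stop("class(es) absent from training labels: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(X) < 20L) stop("need at least 20 training cases", call. = FALSE)
  bad <- setdiff(unique(labels), DIFFICULTY_LABELS)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  Y <- matrix(0, nrow(X), 4L, dimnames = list(NULL, DIFFICULTY_LABELS))
  Y[cbind(seq_len(nrow(X)), match(labels, DIFFICULTY_LABELS))] <- 1

  dims <- c(4L, cfg$hidden_layers, 4L)
  L <- length(dims) - 1L

  .with_seed(cfg$seed, function() {
    n <- nrow(X)
    n_val <- max(1L, floor(cfg$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    Xtr <- X[-val_idx, , drop = FALSE]; Ytr <- Y[-val_idx, , drop = FALSE]
    Xva <- X[val_idx, , drop = FALSE];  Yva <- Y[val_idx, , drop = FALSE]

    params <- list(W = vector("list", L), b = vector("list", L))
    for (l in seq_len(L)) {
      r <- sqrt(6 / (dims[l] + dims[l + 1L]))   # Glorot-uniform init
      params$W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -r, r),
                              dims[l], dims[l + 1L])
      params$b[[l]] <- rep(0, dims[l + 1L])
    }
    mW <- lapply(params$W, function(w) w * 0); vW <- mW
    mb <- lapply(params$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

    best_val <- Inf; best_params <- params; stale <- 0L
    hist_epoch <- integer(0); hist_tl <- numeric(0)
    hist_ta <- numeric(0); hist_vl <- numeric(0)

    for (epoch in seq_len(cfg$max_epochs)) {
      fw <- .forward(params, Xtr)
      ntr <- nrow(Xtr)
      delta <- (fw$prob - Ytr) / ntr      # softmax + cross-entropy gradient
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- t(fw$as[[l]]) %*% delta
        gb[[l]] <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(params$W[[l]])) * (fw$zs[[l - 1L]] > 0)
        }
      }
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mW_hat <- mW[[l]] / (1 - beta1^epoch)
        vW_hat <- vW[[l]] / (1 - beta2^epoch)
        mb_hat <- mb[[l]] / (1 - beta1^epoch)
        vb_hat <- vb[[l]] / (1 - beta2^epoch)
        params$W[[l]] <- params$W[[l]] -
          cfg$learning_rate * mW_hat / (sqrt(vW_hat) + eps)
        params$b[[l]] <- params$b[[l]] -
          cfg$learning_rate * mb_hat / (sqrt(vb_hat) + eps)
      }
      train_loss <- .xent(fw$prob, Ytr)
      train_acc <- mean(max.col(fw$prob, ties.method = "first") ==
                          max.col(Ytr, ties.method = "first"))
      val_loss <- .xent(.forward(params, Xva)$prob, Yva)
      hist_epoch <- c(hist_epoch, epoch)
      hist_tl <- c(hist_tl, train_loss)
      hist_ta <- c(hist_ta, train_acc)
      hist_vl <- c(hist_vl, val_loss)
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss; best_params <- params; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$early_stop_patience) break
      }
    }
    structure(
      list(
        config = cfg,
        weights = best_params,
        class_order = DIFFICULTY_LABELS,
        training_history = tibble::tibble(
          epoch = hist_epoch, train_loss = hist_tl,
          train_accuracy = hist_ta, val_loss = hist_vl
        )
      ),
      class = "molar_net"
    )
  })
}

#' Predict difficulty classes from feature scores
#'
#' @param object A trained `molar_net`.
#' @param newdata Feature scores (see [train_classifier()]); components
#'   outside their scales are an error.
#' @param type `"class"` for labels (argmax, ties broken toward the lower
#'   class) or `"prob"` for the softmax probability matrix (rows sum to 1).
#' @param ... Unused.
#' @return Character vector of labels, or a numeric matrix of class
#'   probabilities with columns D1..D4.
#' @export
predict.molar_net <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- .feature_matrix(newdata)
  prob <- .forward(object$weights, X)$prob
  colnames(prob) <- object$class_order
  if (type == "prob") return(prob)
  object$class_order[max.col(prob, ties.method = "first")]
}

#' @export
print.molar_net <- function(x, ...) {
  cat("<molar_net> 4 -", paste(x$config$hidden_layers, collapse = " - "),
      "- 4 (softmax);", nrow(x$training_history), "epochs trained\n")
  invisible(x)
}
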