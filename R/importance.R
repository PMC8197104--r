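# Relative importance of the four PET inputs (air temperature, mean
# radiant temperature, wind speed, relative humidity) for accident
# outcomes, via a single-hidden-layer neural network and a connection
# weight decomposition of its fitted weights.

#' Build the feature/target table for the importance network
#'
#' One row per working station-hour: features are the hour's weather
#' fields, targets are the number (or presence) of fatal and injury events
#' linked to that station-hour.
#'
#' @param linked Linked events (from [link_accidents()]).
#' @param climate Climate feed covering the same period.
#' @param window Optional POSIXct length-2 vector restricting the period.
#' @param encoding `"count"` (events per hour) or `"binary"` (any event).
#' @param working_hours Inclusive start/end clock hours of the working day.
#' @return A tibble with `city`, `district`, `timestamp`, features `ta`,
#'   `tmrt`, `v`, `rh` and targets `fatal`, `injury`.
#' @export
build_dataset <- function(linked, climate, window = NULL,
                          encoding = c("count", "binary"),
                          working_hours = c(7, 17)) {
  encoding <- match.arg(encoding)
  cl <- climate
  if (!is.null(window)) {
    cl <- cl[cl$timestamp >= window[1] & cl$timestamp <= window[2], ]
  }
  cl <- cl[.is_working_hour(cl$timestamp, working_hours), ]
  if (nrow(cl) == 0) {
    stop("no working station-hours in the requested window", call. = FALSE)
  }
  counts <- dplyr::count(
    dplyr::mutate(linked, .hour = .truncate_hour(.data$timestamp)),
    .data$city, .data$district, .data$.hour, .data$severity)
  counts <- tidyr::pivot_wider(counts, names_from = "severity",
                               values_from = "n", values_fill = 0L)
  for (col in c("fatal", "injury")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- dplyr::left_join(
    dplyr::mutate(cl, .hour = .truncate_hour(.data$timestamp)),
    counts[c("city", "district", ".hour", "fatal", "injury")],
    by = c("city", "district", ".hour"))
  out$fatal[is.na(out$fatal)] <- 0L
  out$injury[is.na(out$injury)] <- 0L
  if (encoding == "binary") {
    out$fatal <- as.integer(out$fatal > 0)
    out$injury <- as.integer(out$injury > 0)
  }
  out$.hour <- NULL
  dplyr::select(out, "city", "district", "timestamp",
                "ta", "tmrt", "v", "rh", "fatal", "injury")
}

#' Network specification for the importance analysis
#'
#' A 4-input, single-hidden-layer, 2-output logistic network: inputs are
#' the four PET environmental factors (min-max scaled to `[0, 1]`),
#' outputs are the fatal-incident and injury targets, and 70% of the rows
#' train the network while the remaining 30% measure R-squared.
#'
#' @param hidden_units Hidden units in the single hidden layer.
#' @param train_fraction Fraction of rows used for training, in (0, 1).
#' @param seed Integer seed for the split and the initial weights.
#' @param maxit Maximum training iterations.
#' @param decay Ridge penalty on the weights. The small default keeps the
#'   weights of uninformative inputs near zero, which the connection-weight
#'   importance decomposition requires: with no penalty, an input that the
#'   fitted function ignores can still carry large mutually-cancelling
#'   weights and inherit spurious importance.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(hidden_units = 9, train_fraction = 0.70, seed = 1L,
                         maxit = 2000, decay = 1e-3) {
  if (hidden_units < 1) stop("`hidden_units` must be >= 1", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(list(hidden_units = as.integer(hidden_units),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 maxit = maxit, decay = decay),
            class = "network_spec")
}

.minmax_scale <- function(x) {
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  scaled <- sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
  list(x = scaled, min = rng[1, ], span = span)
}

#' Train the importance network
#'
#' Fits the logistic feed-forward network of `spec` to the feature/target
#' table with `nnet` (BFGS least-squares optimisation), after min-max
#' scaling of the features and of each target column to `[0, 1]`.
#' R-squared on the held-out split is `1 - SSE/SST` pooled over both
#' outputs (0 by convention when SST is 0).
#'
#' @param table A table from [build_dataset()] (columns `ta`, `tmrt`, `v`,
#'   `rh`, `fatal`, `injury`), with at least 100 rows.
#' @param spec A [network_spec()].
#' @return An object of class `comfort_nn`: the fitted `nnet`, the input
#'   and output weight matrices, the test R-squared and diagnostics.
#' @export
train_network <- function(table, spec = network_spec()) {
  features <- c("ta", "tmrt", "v", "rh")
  targets <- c("fatal", "injury")
  if (nrow(table) < 100) stop("need at least 100 rows", call. = FALSE)
  x <- as.matrix(table[features])
  y <- as.matrix(table[targets])
  sx <- .minmax_scale(x)
  sy <- .minmax_scale(y)

  fit_and_split <- withr::with_seed(spec$seed, {
    n <- nrow(x)
    train <- sample.int(n) <= round(spec$train_fraction * n)
    fit <- nnet::nnet(sx$x[train, , drop = FALSE],
                      sy$x[train, , drop = FALSE],
                      size = spec$hidden_units, decay = spec$decay,
                      maxit = spec$maxit, linout = FALSE, trace = FALSE,
                      MaxNWts = 10000)
    list(fit = fit, train = train)
  })
  fit <- fit_and_split$fit
  train <- fit_and_split$train

  n_in <- length(features); n_h <- spec$hidden_units; n_out <- length(targets)
  w <- fit$wts
  w_hidden <- matrix(w[seq_len(n_h * (n_in + 1))], nrow = n_in + 1)
  w_out <- matrix(w[n_h * (n_in + 1) + seq_len(n_out * (n_h + 1))],
                  nrow = n_h + 1)
  w_input <- w_hidden[-1, , drop = FALSE]      # n_in x n_h
  rownames(w_input) <- features
  w_output <- w_out[-1, , drop = FALSE]        # n_h x n_out
  colnames(w_output) <- targets

  pred <- stats::predict(fit, sx$x[!train, , drop = FALSE])
  obs <- sy$x[!train, , drop = FALSE]
  sst <- sum(sweep(obs, 2, colMeans(obs))^2)
  sse <- sum((obs - pred)^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  converged <- fit$convergence == 0
  if (!converged) {
    warning(sprintf("network training stopped at maxit=%d (final loss %.6g)",
                    spec$maxit, fit$value), call. = FALSE)
  }
  structure(
    list(fit = fit, w_input = w_input, w_output = w_output,
         features = features, targets = targets, r2 = r2,
         final_loss = fit$value, converged = converged,
         spec = spec, train_index = which(train),
         scaling = list(x = sx[c("min", "span")], y = sy[c("min", "span")])),
    class = "comfort_nn")
}

#' @export
print.comfort_nn <- function(x, ...) {
  cat(sprintf("comfort_nn: %d-%d-%d logistic network, test R^2 = %.4f\n",
              length(x$features), x$spec$hidden_units, length(x$targets),
              x$r2))
  invisible(x)
}

#' Connection-weight relative importance
#'
#' Garson's decomposition for a single-hidden-layer network: each input's
#' importance is the sum over hidden units and outputs of its share of the
#' hidden unit's absolute input weight, weighted by the absolute
#' hidden-to-output weight, normalized so the importances sum to 1. The
#' signed Olden variant (sum of products of raw connection weights along
#' each input-hidden-output path) is available via `method = "olden"`; its
#' values are signed and not normalized.
#'
#' @param model A `comfort_nn` from [train_network()], or a list with
#'   elements `w_input` (inputs x hidden) and `w_output` (hidden x
#'   outputs).
#' @param method `"garson"` (default) or `"olden"`.
#' @return A tibble with `variable` and `importance` (plus `r2` attribute
#'   when available).
#' @export
garson_importance <- function(model, method = c("garson", "olden")) {
  method <- match.arg(method)
  w_in <- model$w_input
  w_out <- model$w_output
  vars <- rownames(w_in)
  if (is.null(vars)) vars <- paste0("x", seq_len(nrow(w_in)))
  if (all(w_in == 0) || all(w_out == 0)) {
    stop("importance undefined: all connection weights are zero",
         call. = FALSE)
  }
  if (method == "garson") {
    shares <- abs(w_in)
    colsum <- colSums(shares)
    shares <- sweep(shares, 2, ifelse(colsum == 0, 1, colsum), "/")
    q <- as.numeric(shares %*% rowSums(abs(w_out)))
    q <- q / sum(q)
  } else {
    q <- as.numeric(w_in %*% rowSums(w_out))
  }
  out <- tibble::tibble(variable = vars, importance = q)
  if (!is.null(model$r2)) attr(out, "r2") <- model$r2
  out
}
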