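#' @export
print.mif_model <- function(x, ...) {
  cat(sprintf("<mif_model> call type '%s' (%s, %s-trained), instantiation %d\n",
              x$call_type, x$mode, x$condition, x$instantiation))
  cat(sprintf("  %d feature detector(s) (cap %d)", length(x$fds), x$max_set))
  if (nrow(x$trajectory) > 0) {
    last <- x$trajectory[nrow(x$trajectory), ]
    cat(sprintf("; training hit = %.3f, false alarm = %.3f", last$hit, last$fa))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.mif_model <- function(object, ...) {
  props <- coef(object)
  out <- list(call_type = object$call_type, mode = object$mode,
              condition = object$condition, n_fds = length(object$fds),
              properties = props, trajectory = object$trajectory)
  class(out) <- "summary.mif_model"
  out
}

#' @export
print.summary.mif_model <- function(x, ...) {
  cat(sprintf("MIF model for call type '%s' (%s mode, %s-trained): %d detectors\n\n",
              x$call_type, x$mode, x$condition, x$n_fds))
  if (x$n_fds > 0) {
    cat("Feature-detector properties:\n")
    print(x$properties, digits = 3)
    cat("\nGreedy selection trajectory (hit / false-alarm rates):\n")
    print(x$trajectory, digits = 3)
  }
  invisible(x)
}

#' Feature-detector coefficients of a fitted model
#'
#' One row per selected detector: duration, center frequency, bandwidth,
#' threshold, reduced kurtosis, and the log-likelihood voting weight.
#'
#' @param object a fitted `mif_model`.
#' @param ... unused.
#' @return A `data.frame`, ordered as the detectors were selected.
#' @export
coef.mif_model <- function(object, ...) {
  if (length(object$fds) == 0)
    return(data.frame(id = character(0), duration_ms = numeric(0),
                      center_frequency_hz = numeric(0),
                      bandwidth_oct = numeric(0), threshold = numeric(0),
                      reduced_kurtosis = numeric(0), weight = numeric(0)))
  rows <- lapply(object$fds, function(fd) {
    p <- fd_properties(fd, object$grid)
    cbind(data.frame(id = fd$id), p, data.frame(weight = fd$weight))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict voting scores for new stimuli
#'
#' Applies every detector of the model to each cochleagram and combines the
#' binary detections in the voting stage.
#'
#' @param object a fitted `mif_model`.
#' @param newdata a single cochleagram or a list of cochleagrams.
#' @param mode normalization mode (defaults to the training mode).
#' @param kappa top-down threshold scale, a positive scalar or one value
#'   per stimulus.
#' @param type `"score"` for the voting scores (raw weighted sum and
#'   normalized sum in \[0, 1\]), `"detections"` for the binary detection
#'   matrix (stimuli x detectors).
#' @param ... unused.
#' @return A `data.frame` of scores or a binary matrix.
#' @export
predict.mif_model <- function(object, newdata, mode = object$mode,
                              kappa = 1, type = c("score", "detections"),
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "cochleagram")) newdata <- list(newdata)
  assert_that(length(object$fds) > 0, "cannot predict from an empty model")
  kappa <- rep_len(kappa, length(newdata))
  det <- matrix(0L, length(newdata), length(object$fds))
  for (s in seq_along(newdata))
    for (j in seq_along(object$fds))
      det[s, j] <- fd_detect(object$fds[[j]], newdata[[s]], mode, kappa[s])
  if (type == "detections") {
    colnames(det) <- vapply(object$fds, function(f) f$id, character(1))
    return(det)
  }
  w <- vapply(object$fds, function(f) f$weight, numeric(1))
  data.frame(raw = as.numeric(det %*% w),
             normalized = as.numeric(det %*% w) / sum(w))
}

#' Plot the spectrotemporal receptive fields of a fitted model
#'
#' @param x a fitted `mif_model`.
#' @param n_fds how many detectors to draw (selection order).
#' @param ... passed to [graphics::image()].
#' @export
plot.mif_model <- function(x, n_fds = min(4L, length(x$fds)), ...) {
  assert_that(length(x$fds) > 0, "empty model")
  old <- graphics::par(mfrow = c(1, n_fds), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in seq_len(n_fds)) {
    fd <- x$fds[[j]]
    t <- (seq_len(nrow(fd$strf)) - 0.5) / fd$frame_rate * 1000
    f <- x$grid$frequencies[fd$channel_span[1]:fd$channel_span[2]]
    graphics::image(t, log2(f), fd$strf, xlab = "Time (ms)",
                    ylab = "CF (log2 Hz)", main = fd$id, ...)
  }
  invisible(x)
}

#' @export
print.mif_ensemble <- function(x, ...) {
  cat(sprintf("<mif_ensemble> call type '%s' (%s, %s-trained): %d instantiation(s), %s detectors\n",
              x$call_type, x$mode, x$condition, length(x$models),
              paste(vapply(x$models, function(m) length(m$fds), integer(1)),
                    collapse = "/")))
  invisible(x)
}

#' Serialize a fitted model (or ensemble) to JSON
#'
#' The container stores each detector's patch matrix, channel span,
#' threshold and weight, plus provenance (call type, training condition,
#' mode, seed, instantiation index).
#'
#' @param model a `mif_model` or `mif_ensemble`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_mif_model <- function(model, path) {
  ser_fd <- function(fd) list(id = fd$id, strf = fd$strf,
                              channel_span = fd$channel_span,
                              frame_rate = fd$frame_rate,
                              threshold = fd$threshold, weight = fd$weight)
  ser_model <- function(m) list(
    call_type = m$call_type, mode = m$mode, condition = m$condition,
    instantiation = m$instantiation, max_set = m$max_set,
    rng_seed = m$rng_seed, n_within = m$n_within, n_outside = m$n_outside,
    grid = list(frequencies = m$grid$frequencies,
                step_octaves = m$grid$step_octaves),
    trajectory = m$trajectory,
    fds = lapply(m$fds, ser_fd))
  obj <- if (inherits(model, "mif_ensemble"))
    list(kind = "mif_ensemble", call_type = model$call_type,
         mode = model$mode, condition = model$condition,
         rng_seed = model$rng_seed, models = lapply(model$models, ser_model))
  else c(list(kind = "mif_model"), ser_model(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mif_model
#' @export
read_mif_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  de_fd <- function(f) feature_detector(f$strf, f$channel_span,
                                        frame_rate = f$frame_rate,
                                        threshold = f$threshold,
                                        weight = f$weight, id = f$id)
  de_model <- function(m) {
    grid <- structure(list(frequencies = m$grid$frequencies,
                           step_octaves = m$grid$step_octaves),
                      class = "cf_grid")
    fds <- if (length(m$fds)) lapply(m$fds, de_fd) else list()
    structure(list(fds = fds, call_type = m$call_type, mode = m$mode,
                   condition = m$condition,
                   instantiation = as.integer(m$instantiation),
                   max_set = m$max_set,
                   trajectory = if (length(m$trajectory))
                     do.call(rbind, lapply(m$trajectory, as.data.frame))
                   else data.frame(iteration = integer(0),
                                   candidate = character(0),
                                   mi_bits = numeric(0), hit = numeric(0),
                                   fa = numeric(0)),
                   grid = grid, n_within = m$n_within,
                   n_outside = m$n_outside, rng_seed = m$rng_seed),
              class = "mif_model")
  }
  if (identical(obj$kind, "mif_ensemble")) {
    structure(list(models = lapply(obj$models, de_model),
                   call_type = obj$call_type, mode = obj$mode,
                   condition = obj$condition, rng_seed = obj$rng_seed),
              class = "mif_ensemble")
  } else de_model(obj)
}
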