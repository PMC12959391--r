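# Internal utilities shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fan one global seed out into independent substreams (e.g. per channel),
# keeping the result inside the 32-bit integer range R requires.
substream_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807 + 11) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stream_rate <- function(stream) {
  t <- stream$time_s
  if (length(t) < 2) stop("stream too short to infer a rate", call. = FALSE)
  1 / stats::median(diff(t))
}

stream_channels <- function(stream) {
  grep("^ch[0-9]+$", names(stream), value = TRUE)
}

stream_dofs <- function(stream, skeleton = NULL) {
  dofs <- setdiff(names(stream), c("time_s", "label", "split"))
  dofs <- dofs[!grepl("^ch[0-9]+$", dofs)]
  if (!is.null(skeleton)) dofs <- intersect(skeleton$dof, dofs)
  dofs
}

# Smooth low-frequency pseudo-random wander used as involuntary-motion jitter.
smooth_jitter <- function(t, amp) {
  f1 <- stats::runif(1, 0.08, 0.2); f2 <- stats::runif(1, 0.2, 0.45)
  p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
  a <- stats::runif(1, 0.5, 1)
  amp * (a * sin(2 * pi * f1 * t + p1) + (1 - a) * sin(2 * pi * f2 * t + p2))
}

clip_to_ranges <- function(A, dofs, ranges) {
  lo <- ranges$lo[match(dofs, ranges$dof)]
  hi <- ranges$hi[match(dofs, ranges$dof)]
  for (k in seq_along(dofs)) {
    A[, k] <- pmin(hi[k], pmax(lo[k], A[, k]))
  }
  A
}

angle_stream_tbl <- function(times, A, dofs) {
  colnames(A) <- dofs
  out <- tibble::as_tibble(as.data.frame(A))
  out <- dplyr::bind_cols(tibble::tibble(time_s = times), out)
  class(out) <- c("angle_stream", class(out))
  out
}

protocol_tbl <- function(start_s, end_s, label) {
  out <- tibble::tibble(start_s = start_s, end_s = end_s, label = label)
  class(out) <- c("motion_protocol", class(out))
  out
}

#' Per-frame class labels from a protocol
#'
#' @param times Frame timestamps (seconds).
#' @param protocol A protocol tibble (`start_s`, `end_s`, `label`).
#' @return Character vector, `NA` outside all segments.
#' @export
protocol_labels <- function(times, protocol) {
  lab <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(protocol))) {
    lab[times >= protocol$start_s[i] & times < protocol$end_s[i]] <-
      protocol$label[i]
  }
  lab
}
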