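# Topography ingestion and puff detection.
#
# A flow trace is the raw topography signal: volumetric flow rate at the
# mouthpiece sampled in time.  Puffs are maximal above-threshold runs of the
# trace; each detected puff carries its duration d [s], volume v [mL]
# (trapezoidal integral of flow over the puff window) and volume-weighted
# mean flow q = v / d [mL/s], so that v = q * d holds exactly by
# construction.

#' Construct a flow trace
#'
#' @param time Numeric vector of sample times, seconds, strictly increasing,
#'   non-negative.
#' @param flow Numeric vector of volumetric flow rates, mL/s.  Negative
#'   values (sensor noise around zero) are clipped to 0; the count of
#'   clipped samples is kept in the `n_clipped` attribute.
#' @return A `flow_trace`: a data frame with columns `time` and `flow`.
#' @export
#' @examples
#' tr <- flow_trace(c(0, 0.1, 0.2), c(0, 20, 0))
#' max(tr$flow)
flow_trace <- function(time, flow) {
  if (length(time) != length(flow))
    stop_data("time and flow must have equal length")
  time <- as.double(time); flow <- as.double(flow)
  if (anyNA(time) || any(!is.finite(time)))
    stop_data("non-finite sample times")
  if (anyNA(flow) || any(!is.finite(flow)))
    stop_data("non-finite flow values")
  if (length(time) > 1L) {
    dt <- diff(time)
    if (any(dt == 0))
      stop_data("duplicate timestamps at t = ",
                paste(head(time[which(dt == 0)], 3L), collapse = ", "))
    if (any(dt < 0))
      stop_data("time must be strictly increasing (non-monotone at index ",
                which(dt < 0)[1L] + 1L, ")")
  }
  if (any(time < 0)) stop_data("negative sample times")
  n_clipped <- sum(flow < 0)
  flow[flow < 0] <- 0
  out <- data.frame(time = time, flow = flow)
  class(out) <- c("flow_trace", "data.frame")
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Read a topography flow trace from CSV
#'
#' Expects header `time_s,flow_ml_s`; lines starting with `#` are metadata
#' and skipped.  Negative flows are clipped to zero (counted in the
#' `n_clipped` attribute); duplicate or backwards timestamps are rejected.
#'
#' @param path Path to the CSV file.
#' @return A [flow_trace()].
#' @export
read_flow_trace <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  df <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop_data("cannot parse ", path, ": ", conditionMessage(e)))
  cols <- c("time_s", "flow_ml_s")
  if (!all(cols %in% names(df))) {
    if (ncol(df) < 2L) stop_data(path, ": expected two columns time_s,flow_ml_s")
    names(df)[1:2] <- cols
  }
  tm <- suppressWarnings(as.numeric(df$time_s))
  fl <- suppressWarnings(as.numeric(df$flow_ml_s))
  bad <- which(is.na(tm) | is.na(fl))
  if (length(bad))
    stop_data(path, ": malformed row at data line ", bad[1L])
  flow_trace(tm, fl)
}

#' Write a flow trace to CSV
#'
#' Inverse of [read_flow_trace()]; values are written with enough digits to
#' round-trip within 1e-9 relative.
#'
#' @param trace A `flow_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_trace <- function(trace, path) {
  stopifnot(inherits(trace, "flow_trace"))
  df <- data.frame(time_s = sprintf("%.12g", trace$time),
                   flow_ml_s = sprintf("%.12g", trace$flow))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Detect discrete puffs in a flow trace
#'
#' A puff is a maximal run of samples with flow at or above `threshold`.
#' Runs separated by a below-threshold gap shorter than `min_gap` are merged
#' (the gap is part of the merged puff window); merged runs shorter than
#' `min_duration` are discarded.  Puff volume is the trapezoidal integral of
#' flow over the puff window, duration is the window length, and mean flow
#' is volume / duration.
#'
#' @param trace A [flow_trace()].
#' @param threshold Detection threshold, mL/s (> 0).  Default 1.0.
#' @param min_duration Minimum puff duration, s. Default 0.1.
#' @param min_gap Gaps shorter than this merge adjacent runs, s. Default 0.3.
#' @return A `puff_set`: data frame with columns `start`, `duration`,
#'   `volume`, `mean_flow`, one row per detected puff, time-ordered and
#'   non-overlapping.  Empty traces yield zero rows.
#' @export
#' @examples
#' t <- seq(0, 4, by = 0.01)
#' tr <- flow_trace(t, ifelse(t >= 1 & t <= 2.2, 30, 0))
#' detect_puffs(tr)
detect_puffs <- function(trace, threshold = 1.0, min_duration = 0.1,
                         min_gap = 0.3) {
  stopifnot(inherits(trace, "flow_trace"))
  check_number(threshold, "threshold", positive = TRUE)
  check_number(min_duration, "min_duration", non_negative = TRUE)
  check_number(min_gap, "min_gap", non_negative = TRUE)
  empty <- data.frame(start = double(), duration = double(),
                      volume = double(), mean_flow = double())
  class(empty) <- c("puff_set", "data.frame")
  if (nrow(trace) == 0L) return(empty)

  above <- trace$flow >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  # merge runs separated by short sub-threshold gaps
  merged <- list()
  cur <- runs[1L, ]
  if (nrow(runs) > 1L) for (k in 2:nrow(runs)) {
    gap <- trace$time[runs[k, 1L]] - trace$time[cur[2L]]
    if (gap < min_gap) cur[2L] <- runs[k, 2L]
    else { merged[[length(merged) + 1L]] <- cur; cur <- runs[k, ] }
  }
  merged[[length(merged) + 1L]] <- cur

  rows <- lapply(merged, function(w) {
    i <- w[1L]:w[2L]
    d <- trace$time[w[2L]] - trace$time[w[1L]]
    if (d < min_duration || d <= 0) return(NULL)
    v <- trapz(trace$time[i], trace$flow[i])
    data.frame(start = trace$time[w[1L]], duration = d,
               volume = v, mean_flow = v / d)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("puff_set", "data.frame")
  out
}

#' Construct a puffing session
#'
#' A session groups the time-ordered puffs of one continuous use episode by
#' one participant.
#'
#' @param puffs A `puff_set` data frame (columns `start`, `duration`,
#'   `volume`, `mean_flow`) with at least one puff.
#' @param session_id,participant_id Identifying labels.
#' @return A `puff_session` object.
#' @export
puff_session <- function(puffs, session_id = "session",
                         participant_id = "participant") {
  puffs <- as.data.frame(puffs)
  need <- c("start", "duration", "volume", "mean_flow")
  if (!all(need %in% names(puffs)))
    stop_data("puffs must have columns ", paste(need, collapse = ", "))
  if (nrow(puffs) < 1L) stop_data("a session needs at least one puff")
  if (any(puffs$duration <= 0)) stop_data("puff durations must be > 0")
  if (any(puffs$volume <= 0)) stop_data("puff volumes must be > 0")
  rel <- abs(puffs$mean_flow * puffs$duration - puffs$volume) /
    pmax(puffs$volume, .Machine$double.eps)
  if (any(rel > 1e-9))
    stop_data("mean_flow * duration must equal volume (max rel err ",
              signif(max(rel), 3), ")")
  if (is.unsorted(puffs$start, strictly = TRUE))
    stop_data("puffs must be strictly time-ordered")
  stops <- puffs$start + puffs$duration
  if (nrow(puffs) > 1L && any(puffs$start[-1L] < stops[-nrow(puffs)]))
    stop_data("puffs must not overlap")
  structure(list(session_id = as.character(session_id),
                 participant_id = as.character(participant_id),
                 puffs = puffs),
            class = "puff_session")
}

#' @export
print.puff_session <- function(x, ...) {
  s <- session_summary(x)
  cat(sprintf(
    "Puffing session '%s' (participant %s): %d puffs\n  mean duration %.2f s, mean flow %.1f mL/s, total volume %.1f mL\n",
    x$session_id, x$participant_id, s[["n_puffs"]], s[["mean_d"]],
    s[["mean_q"]], s[["total_volume"]]))
  invisible(x)
}

#' Session-level topography summary
#'
#' Arithmetic mean puff duration and mean puff flow rate, total puff volume
#' and puff count — the per-session statistics used to characterise
#' playback profiles.
#'
#' @param session A [puff_session()].
#' @return Named numeric vector `(mean_d, mean_q, total_volume, n_puffs)`.
#' @export
session_summary <- function(session) {
  stopifnot(inherits(session, "puff_session"))
  p <- session$puffs
  if (nrow(p) < 1L) stop_data("empty session")
  c(mean_d = mean(p$duration), mean_q = mean(p$mean_flow),
    total_volume = sum(p$volume), n_puffs = nrow(p))
}

#' Inter-puff intervals of a session
#'
#' Interval i between consecutive puffs: next start minus current end, s.
#'
#' @param session A [puff_session()].
#' @return Numeric vector of length `n_puffs - 1`.
#' @export
puff_intervals <- function(session) {
  stopifnot(inherits(session, "puff_session"))
  p <- session$puffs
  if (nrow(p) < 2L) return(double())
  p$start[-1L] - (p$start[-nrow(p)] + p$duration[-nrow(p)])
}

#' Read a session: topography CSV plus YAML sidecar
#'
#' Reads `<path>` as a flow trace, detects puffs, and attaches
#' `session_id` / `participant_id` from `<path>.yaml` (or `.yml`) when the
#' sidecar exists.
#'
#' @param path Topography CSV path.
#' @inheritParams detect_puffs
#' @return A [puff_session()].
#' @export
read_session <- function(path, threshold = 1.0, min_duration = 0.1,
                         min_gap = 0.3) {
  trace <- read_flow_trace(path)
  puffs <- detect_puffs(trace, threshold, min_duration, min_gap)
  if (nrow(puffs) == 0L) stop_data(path, ": no puffs detected")
  meta <- list(session_id = sub("\\.csv$", "", basename(path)),
               participant_id = "unknown")
  for (side in paste0(path, c(".yaml", ".yml"))) {
    if (file.exists(side)) {
      y <- yaml::read_yaml(side)
      meta$session_id <- y$session_id %||% meta$session_id
      meta$participant_id <- y$participant_id %||% meta$participant_id
      break
    }
  }
  puff_session(puffs, meta$session_id, meta$participant_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a session's trace and sidecar
#'
#' @param trace The `flow_trace` to write.
#' @param session The `puff_session` whose identifiers go into the sidecar.
#' @param path Output CSV path; `<path>.yaml` is written alongside.
#' @return `path`, invisibly.
#' @export
write_session <- function(trace, session, path) {
  write_flow_trace(trace, path)
  yaml::write_yaml(list(session_id = session$session_id,
                        participant_id = session$participant_id),
                   paste0(path, ".yaml"))
  invisible(path)
}
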