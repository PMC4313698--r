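#' Delay and distance labels used by the audio-tactile interaction task
#'
#' The tactile stimulus is delivered at one of five delays from sound onset
#' (T1-T5 = 300, 800, 1500, 2200, 2700 ms). For sounds approaching the hand
#' (IN) later touches coincide with nearer perceived sound positions; for
#' receding sounds (OUT) the mapping reverses. Delays are therefore recoded
#' to perceived-distance bins D1 (farthest) to D5 (closest).
#'
#' @format `pps_delays` is a named numeric vector (T1-T5, ms).
#' @export
pps_delays <- c(T1 = 300, T2 = 800, T3 = 1500, T4 = 2200, T5 = 2700)

#' Recode a delay label to a perceived-distance label
#'
#' IN sounds: T1 -> D1 (farthest) ... T5 -> D5 (closest); OUT sounds:
#' T1 -> D5 ... T5 -> D1. The recoding is a bijection for each direction.
#'
#' @param direction `"IN"` or `"OUT"` (vectorized, recycled as usual).
#' @param delay_label `"T1"`..`"T5"`.
#' @return distance label `"D1"`..`"D5"`.
#' @examples
#' recode_distance("IN", "T1")   # "D1"
#' recode_distance("OUT", "T1")  # "D5"
#' @export
recode_distance <- function(direction, delay_label) {
  if (!all(direction %in% c("IN", "OUT")))
    stop("invalid direction label; expected IN or OUT")
  if (!all(delay_label %in% paste0("T", 1:5)))
    stop("invalid delay label; expected T1..T5")
  idx <- as.integer(substring(delay_label, 2))
  d <- ifelse(direction == "IN", idx, 6L - idx)
  paste0("D", d)
}

#' Read a trial-level reaction-time table
#'
#' Strict reader for delimited trial tables with columns `subject`,
#' `condition` (synchronous/asynchronous), `session` (before/after1/after2),
#' `direction` (IN/OUT), `delay` (T1..T5), `rt` (ms; NA on catch trials) and
#' `catch` (logical). Labels are validated; a `distance` column (D1..D5) is
#' added via [recode_distance()].
#'
#' @param path file path (tab- or comma-separated, with header).
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return data.frame of trials.
#' @export
read_trials <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path)
  if (is.null(sep)) {
    l1 <- readLines(path, n = 1)
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  validate_trials(d)
}

validate_trials <- function(d) {
  need <- c("subject", "condition", "session", "direction", "delay", "rt",
            "catch")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(d$condition %in% c("synchronous", "asynchronous")))
    stop("invalid condition labels")
  if (!all(d$session %in% c("before", "after1", "after2")))
    stop("invalid session labels")
  if (!all(d$direction %in% c("IN", "OUT"))) stop("invalid direction labels")
  if (!all(d$delay %in% paste0("T", 1:5))) stop("invalid delay labels")
  d$catch <- as.logical(d$catch)
  if (any(d$catch & !is.na(d$rt)))
    stop("catch trials must not carry reaction times")
  if (any(!d$catch & (is.na(d$rt) | d$rt <= 0)))
    stop("tactile trials must carry positive reaction times ",
         "(drop missed detections before reading)")
  d$distance <- recode_distance(d$direction, d$delay)
  d
}

#' Trim outlying reaction times at two standard deviations
#'
#' Single-pass trimming: within each subject x condition cell (granularity
#' configurable), the mean and standard deviation are computed once and
#' trials with `|rt - mean| > 2 sd` are removed. Catch trials are excluded
#' beforehand.
#'
#' @param trials validated trial data.frame (see [read_trials()]).
#' @param by grouping columns defining the trimming cell (default
#'   `c("subject", "condition")`).
#' @param n_sd trimming threshold in standard deviations (default 2).
#' @return list with `trials` (kept rows) and `report` (per-cell counts of
#'   removed trials).
#' @export
trim_outliers <- function(trials, by = c("subject", "condition"), n_sd = 2) {
  t2 <- trials[!trials$catch & !is.na(trials$rt), , drop = FALSE]
  if (nrow(t2) == 0)
    return(list(trials = t2,
                report = data.frame(cell = character(), n = integer(),
                                    removed = integer())))
  cell <- interaction(t2[by], drop = TRUE, sep = ":")
  keep <- rep(TRUE, nrow(t2))
  rep_rows <- list()
  for (cl in levels(cell)) {
    i <- which(cell == cl)
    m <- mean(t2$rt[i]); s <- stats::sd(t2$rt[i])
    out <- if (is.na(s) || s == 0) rep(FALSE, length(i)) else
      abs(t2$rt[i] - m) > n_sd * s
    keep[i[out]] <- FALSE
    rep_rows[[cl]] <- data.frame(cell = cl, n = length(i),
                                 removed = sum(out))
  }
  list(trials = t2[keep, , drop = FALSE],
       report = do.call(rbind, c(rep_rows, make.row.names = FALSE)))
}

#' Summarize reaction times per condition, session, direction and distance
#'
#' Balanced two-stage aggregation: subject means are computed first, cell
#' means and SEMs are then taken across subjects, so subjects with more
#' retained trials do not dominate.
#'
#' @param trials post-trim trial data.frame.
#' @return data.frame with `condition`, `session`, `direction`, `distance`,
#'   `mean`, `sem` (NA when only one subject contributes), `n_subjects`.
#' @export
summarize_rt <- function(trials) {
  subj <- stats::aggregate(
    rt ~ subject + condition + session + direction + distance,
    data = trials, FUN = mean)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  out <- stats::aggregate(
    rt ~ condition + session + direction + distance, data = subj,
    FUN = function(v) c(mean = mean(v), sem = sem(v), n = length(v)))
  res <- data.frame(out[, c("condition", "session", "direction", "distance")],
                    mean = out$rt[, "mean"], sem = out$rt[, "sem"],
                    n_subjects = out$rt[, "n"])
  res[order(res$condition, res$session, res$direction, res$distance), ]
}

#' Fit the boundary sigmoid per session (IN sounds)
#'
#' For each session of one training condition, fits reaction time against
#' the touch-delivery time (ms) for IN sounds, pooling the two post-training
#' blocks into one "after" session by default (set `pool_after = FALSE` to
#' fit them separately). The central point `xc` (ms of touch delay) is the
#' operational boundary of peripersonal space: smaller values mean the
#' approaching sound starts affecting touch earlier, i.e. farther from the
#' body.
#'
#' @param trials post-trim trial data.frame.
#' @param condition training condition to analyze.
#' @param pool_after pool `after1`/`after2` into one session (default TRUE).
#' @param on_means fit session-cell subject-pooled mean RTs (one point per
#'   delay) instead of trial-level data; default FALSE (pooled trials).
#' @return named list of `boundary_fit` objects (one per session).
#' @export
boundary_per_session <- function(trials,
                                 condition = c("synchronous", "asynchronous"),
                                 pool_after = TRUE, on_means = FALSE) {
  condition <- match.arg(condition)
  t2 <- trials[trials$condition == condition & trials$direction == "IN" &
                 !trials$catch & !is.na(trials$rt), , drop = FALSE]
  if (nrow(t2) == 0) stop("no IN-sound trials for condition ", condition)
  sess <- if (pool_after)
    ifelse(t2$session == "before", "before", "after")
  else t2$session
  fits <- list()
  for (sl in unique(sess)) {
    ti <- t2[sess == sl, , drop = FALSE]
    x <- unname(pps_delays[ti$delay])
    y <- ti$rt
    if (length(unique(x)) < 4) {
      warning("session ", sl, ": fewer than 4 delay cells with data; skipped")
      next
    }
    if (on_means) {
      my <- tapply(y, x, mean)
      x <- as.numeric(names(my)); y <- as.numeric(my)
    }
    fits[[sl]] <- fit_sigmoid(x, y)
  }
  fits
}
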