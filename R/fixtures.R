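#' Bundled group-level reaction-time means from the behavioral experiment
#'
#' Published group means (+/- SEM, ms) of tactile reaction times in the
#' audio-tactile interaction task, by training condition, session, sound
#' direction and perceived distance bin (D1 farthest .. D5 closest).
#' IN-sound means for the asynchronous condition were reported pooled over
#' sessions (the session effect was not significant) and are stored with
#' `session = "pooled"`. The after-training IN-sound mean at D1 was not
#' reported; the cell is present with `NA` and `missing = TRUE`.
#'
#' @return data.frame with columns `condition`, `session`, `direction`,
#'   `distance`, `mean`, `sem`, `missing`.
#' @examples
#' m <- reference_rt_means()
#' subset(m, condition == "synchronous" & session == "before" &
#'          direction == "IN")
#' @export
reference_rt_means <- function() {
  row <- function(cond, sess, dir, means, sems) {
    data.frame(condition = cond, session = sess, direction = dir,
               distance = paste0("D", 1:5), mean = means, sem = sems,
               missing = is.na(means))
  }
  rbind(
    row("synchronous", "before", "IN", c(517, 497, 464, 459, 455),
        c(23, 24, 22, 23, 26)),
    row("synchronous", "after", "IN", c(NA, 470, 450, 439, 439),
        c(NA, 23, 22, 22, 22)),
    row("asynchronous", "pooled", "IN", c(484, 481, 444, 440, 433),
        c(24, 26, 25, 28, 25)),
    row("synchronous", "before", "OUT", c(505, 474, 460, 476, 477),
        c(27, 24, 25, 25, 26)),
    row("synchronous", "after", "OUT", c(466, 451, 447, 457, 445),
        c(26, 23, 23, 23, 23)),
    row("asynchronous", "before", "OUT", c(466, 443, 426, 447, 449),
        c(22, 22, 21, 20, 23)),
    row("asynchronous", "after", "OUT", c(485, 471, 457, 474, 451),
        c(27, 31, 32, 30, 29))
  )
}

#' Specification for a synthetic behavioral reaction-time dataset
#'
#' Describes the generative model used by [generate_rt_dataset()]: a true
#' boundary sigmoid on the touch-delivery time (IN-sound convention),
#' additive subject intercepts, Gaussian trial noise, a configurable rate
#' of late-outlier trials, and catch trials without touch.
#'
#' @param ymin,ymax,xc,b true sigmoid parameters ([boundary_sigmoid()];
#'   `b < 0` for the usual decreasing RT-vs-delay curve).
#' @param n_subjects number of subjects.
#' @param trials_per_cell tactile trials per subject x direction x delay cell.
#' @param noise_sd trial-level Gaussian noise SD, ms.
#' @param subject_sd SD of the subject random intercept, ms.
#' @param outlier_rate fraction of tactile trials replaced by late outliers.
#' @param outlier_shift added to the cell mean on outlier trials, ms.
#' @param catch_frac fraction of trials that are catch trials (sound only).
#' @return a `synthetic_rt_spec` object.
#' @export
synthetic_rt_spec <- function(ymin = 450, ymax = 65, xc = 1100, b = -250,
                              n_subjects = 16, trials_per_cell = 6,
                              noise_sd = 40, subject_sd = 20,
                              outlier_rate = 0.02, outlier_shift = 350,
                              catch_frac = 0.23) {
  if (noise_sd <= 0) stop("configuration error: noise_sd must be > 0")
  if (trials_per_cell < 1) stop("configuration error: trials_per_cell >= 1")
  if (b == 0) stop("configuration error: b must be nonzero")
  structure(list(ymin = ymin, ymax = ymax, xc = xc, b = b,
                 n_subjects = n_subjects, trials_per_cell = trials_per_cell,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 outlier_rate = outlier_rate, outlier_shift = outlier_shift,
                 catch_frac = catch_frac),
            class = "synthetic_rt_spec")
}

#' Generate a synthetic trial-level reaction-time table
#'
#' Emulates the structure the behavioral pipeline assumes: each trial's RT
#' is the true sigmoid evaluated at the touch-delivery time matched to the
#' trial's perceived distance bin (so IN and OUT trials with the same bin
#' share a latent mean), plus a subject intercept and Gaussian noise;
#' a configurable fraction of trials are replaced by late outliers, and
#' catch trials carry no RT. The result validates under the strict trial
#' reader and is reproducible under `set.seed()`.
#'
#' @param spec a [synthetic_rt_spec()].
#' @param condition,session labels to stamp on the table.
#' @param directions sound directions to generate.
#' @return trial data.frame (`subject`, `condition`, `session`, `direction`,
#'   `delay`, `rt`, `catch`, `distance`).
#' @export
generate_rt_dataset <- function(spec, condition = "synchronous",
                                session = "before",
                                directions = c("IN", "OUT")) {
  stopifnot(inherits(spec, "synthetic_rt_spec"))
  delays <- pps_delays
  rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    intercept <- stats::rnorm(1, 0, spec$subject_sd)
    for (dir in directions) for (tl in names(delays)) {
      dist <- recode_distance(dir, tl)
      # latent mean indexed by perceived distance: the IN-sound delay
      # mapped to the same bin
      x_lat <- unname(delays[paste0("T", substring(dist, 2))])
      mu <- boundary_sigmoid(x_lat, spec$ymin, spec$ymax, spec$xc, spec$b) +
        intercept
      n <- spec$trials_per_cell
      rt <- mu + stats::rnorm(n, 0, spec$noise_sd)
      out <- stats::runif(n) < spec$outlier_rate
      rt[out] <- mu + spec$outlier_shift + abs(stats::rnorm(sum(out), 0, 50))
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("S%02d", s), condition = condition,
        session = session, direction = dir, delay = tl, rt = rt,
        catch = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  n_catch <- round(spec$catch_frac / (1 - spec$catch_frac) * nrow(d))
  if (n_catch > 0) {
    i <- sample(nrow(d), n_catch, replace = TRUE)
    cd <- d[i, ]; cd$rt <- NA_real_; cd$catch <- TRUE
    d <- rbind(d, cd)
  }
  d <- d[sample(nrow(d)), ]
  rownames(d) <- NULL
  validate_trials(d)
}
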