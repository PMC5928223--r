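#' Build an ascending geometric concentration series
#'
#' Constructs the dilution ladder used for orosensory detection-threshold
#' testing: `n_steps` concentrations starting at `c_min` and spaced by
#' `step_log10` log10 units, i.e. `c_min * 10^(step_log10 * k)` for
#' `k = 0, ..., n_steps - 1`. The default arguments give the 18-solution
#' linoleic-acid (LA) ladder from 0.00028% to about 5% (wt/wt) in 0.25
#' log-unit steps.
#'
#' The series is built by step count rather than by endpoint: 18 quarter-log
#' steps from 0.00028% land within 0.5% relative of 5%, not exactly on it.
#'
#' @param c_min lowest concentration, % wt/wt (> 0).
#' @param step_log10 spacing between consecutive solutions in log10 units (> 0).
#' @param n_steps number of solutions (>= 1).
#' @return An object of class `"concentration_series"`: a list with
#'   `concentrations` (increasing numeric vector), `c_min`, `step_log10`
#'   and `n_steps`.
#' @examples
#' s <- build_concentration_series()
#' length(s$concentrations)  # 18
#' s$concentrations[5]       # 0.0028 (= 0.00028 * 10, four quarter-log steps)
#' @export
build_concentration_series <- function(c_min = 0.00028, step_log10 = 0.25,
                                       n_steps = 18L) {
  stopifnot(is.numeric(c_min), length(c_min) == 1, c_min > 0)
  if (!is.numeric(step_log10) || length(step_log10) != 1 || step_log10 <= 0) {
    stop("`step_log10` must be a positive number")
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1) {
    stop("`n_steps` must be >= 1")
  }
  n_steps <- as.integer(n_steps)
  conc <- c_min * 10^(step_log10 * (seq_len(n_steps) - 1))
  structure(
    list(concentrations = conc, c_min = c_min, step_log10 = step_log10,
         n_steps = n_steps),
    class = "concentration_series"
  )
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf(
    "Ascending concentration series: %d solutions, %.5g%% to %.4g%% (wt/wt), %.3g log10 steps\n",
    x$n_steps, x$c_min, max(x$concentrations), x$step_log10))
  invisible(x)
}

#' Determine the detection threshold from 3-AFC trials
#'
#' Applies the ascending-procedure stop rule: the threshold is the first
#' concentration identified correctly three times consecutively. A streak
#' is broken by an incorrect response or by a change of concentration. If
#' no concentration ever accumulates three consecutive correct responses,
#' the subject is censored at the top of the series.
#'
#' @param trials data frame with columns `concentration` (non-decreasing,
#'   positive) and `correct` (logical).
#' @return list with `threshold` (% wt/wt; the series maximum presented when
#'   censored) and `censored` (logical).
#' @examples
#' tr <- data.frame(concentration = c(1, 2, 2, 2), correct = c(FALSE, TRUE, TRUE, TRUE))
#' detect_threshold(tr)  # threshold 2, not censored
#' @export
detect_threshold <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0,
            all(c("concentration", "correct") %in% names(trials)))
  conc <- trials$concentration
  ok <- as.logical(trials$correct)
  if (any(diff(conc) < 0)) stop("trial concentrations must be non-decreasing")
  streak <- 0L
  streak_conc <- NA_real_
  for (i in seq_along(conc)) {
    if (ok[i]) {
      if (streak > 0L && isTRUE(conc[i] == streak_conc)) {
        streak <- streak + 1L
      } else {
        streak <- 1L
        streak_conc <- conc[i]
      }
      if (streak >= 3L) {
        return(list(threshold = streak_conc, censored = FALSE))
      }
    } else {
      streak <- 0L
    }
  }
  list(threshold = max(conc), censored = TRUE)
}

#' Simulate a 3-AFC ascending threshold session
#'
#' Simulates one subject working up the concentration ladder under the
#' three-alternative forced-choice protocol. Below the subject's true
#' threshold a response is correct with probability `guess_rate` (chance is
#' 1/3 with three cups); at or above it, with probability `1 - lapse_rate`.
#' After a correct identification the same concentration is presented again;
#' after an incorrect one the series advances one step. The session stops at
#' three consecutive correct identifications of one concentration, or is
#' censored at the series maximum.
#'
#' @param series a `"concentration_series"`.
#' @param true_threshold the subject's true detection threshold, % wt/wt.
#' @param guess_rate probability of a correct answer below threshold
#'   (default 1/3).
#' @param lapse_rate probability of an incorrect answer at or above threshold
#'   (default 0).
#' @param subject_id identifier stored in the session.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `"afc_session"`: list with `subject_id`,
#'   `trials` (data frame of `concentration`, `correct`), `threshold` and
#'   `censored`.
#' @examples
#' s <- build_concentration_series()
#' sess <- simulate_3afc_session(s, true_threshold = s$concentrations[11],
#'                               guess_rate = 0)
#' sess$threshold == s$concentrations[11]
#' @export
simulate_3afc_session <- function(series, true_threshold, guess_rate = 1 / 3,
                                  lapse_rate = 0, subject_id = "subject",
                                  seed = NULL) {
  stopifnot(inherits(series, "concentration_series"),
            is.numeric(true_threshold), length(true_threshold) == 1,
            guess_rate >= 0, guess_rate <= 1,
            lapse_rate >= 0, lapse_rate <= 1)
  conc <- series$concentrations
  with_seed(seed, {
    trials_c <- numeric(0)
    trials_ok <- logical(0)
    i <- 1L
    streak <- 0L
    threshold <- NA_real_
    censored <- TRUE
    while (i <= length(conc)) {
      p_correct <- if (conc[i] < true_threshold) guess_rate else 1 - lapse_rate
      ok <- stats::runif(1) < p_correct
      trials_c <- c(trials_c, conc[i])
      trials_ok <- c(trials_ok, ok)
      if (ok) {
        streak <- streak + 1L
        if (streak >= 3L) {
          threshold <- conc[i]
          censored <- FALSE
          break
        }
        # same concentration presented again
      } else {
        streak <- 0L
        i <- i + 1L
      }
    }
    if (censored) threshold <- max(conc)
    structure(
      list(subject_id = subject_id,
           trials = data.frame(concentration = trials_c, correct = trials_ok),
           threshold = threshold, censored = censored),
      class = "afc_session"
    )
  })
}

#' Classify subjects as lipid tasters or non-tasters
#'
#' A subject whose detection threshold is at or above the cutoff (0.5% LA
#' wt/wt by convention), or who never met the stop criterion (censored at the
#' series maximum), is a non-taster (`"NT"`); all others are tasters (`"T"`).
#'
#' @param threshold numeric vector of detection thresholds, % wt/wt.
#' @param censored logical vector (recycled) flagging censored subjects.
#' @param cutoff taster/non-taster cutoff, % wt/wt (> 0, default 0.5).
#' @return character vector of labels `"T"` / `"NT"`.
#' @examples
#' classify_taster(c(0.499, 0.5, 5), censored = c(FALSE, FALSE, TRUE))
#' @export
classify_taster <- function(threshold, censored = FALSE, cutoff = 0.5) {
  stopifnot(is.numeric(threshold), is.numeric(cutoff), length(cutoff) == 1,
            cutoff > 0)
  censored <- rep_len(as.logical(censored), length(threshold))
  ifelse(censored | threshold >= cutoff, "NT", "T")
}

#' Geometric mean of detection thresholds
#'
#' Thresholds span several orders of magnitude, so group summaries are
#' geometric means: `exp(mean(log(x)))`.
#'
#' @param thresholds numeric vector of positive thresholds.
#' @return the geometric mean.
#' @examples
#' geometric_mean_threshold(c(0.01, 1))  # 0.1
#' @export
geometric_mean_threshold <- function(thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop("all thresholds must be positive and finite")
  }
  exp(mean(log(thresholds)))
}
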