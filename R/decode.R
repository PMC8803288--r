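#' Map decoded HMM states to ethogram behaviors
#'
#' Converts the five states of the fitted model into the four behaviors
#' rest, sing, fly, leap. States are ordered by emission standard deviation
#' (ascending, ties broken by state index): the two quietest states are both
#' inactive (`rest`), the middle state is the medium-amplitude body vibration
#' of song (`sing`). Of the two most active states, emission scale alone
#' cannot separate sustained flight from brief prey-chasing leaps, so the
#' state with the longer mean decoded run length becomes `fly` and the other
#' `leap`.
#'
#' @param model A fitted `gaussian_hmm` with `K = 5`, unless `map` is given.
#' @param states Integer Viterbi state sequence at 25 Hz, used for the
#'   run-length disambiguation of fly vs leap.
#' @param map Optional user-supplied named character vector
#'   (`c("1" = "rest", ...)`); when given, it is validated and returned
#'   unchanged and `K` may differ from 5.
#' @return Named character vector of length `K` mapping state index to
#'   behavior.
#' @export
map_states_to_behaviors <- function(model, states = NULL, map = NULL) {
  stopifnot(inherits(model, "gaussian_hmm"))
  if (!is.null(map)) {
    stopifnot(length(map) == model$K, all(map %in% BEHAVIORS))
    names(map) <- as.character(seq_len(model$K))
    return(map)
  }
  if (model$K != 5)
    stop("automatic state mapping requires K = 5; supply an explicit map for K = ",
         model$K)
  if (is.null(states)) stop("a decoded state sequence is required to separate fly from leap")
  ord <- order(model$sigma, seq_len(model$K))  # ascending sd, index tie-break
  top2 <- ord[4:5]
  mrl <- vapply(top2, function(s) {
    r <- rle(states)
    runs <- r$lengths[r$values == s]
    if (length(runs) == 0) 0 else mean(runs)
  }, 0)
  # longer sustained runs -> flight; ties go to the lower state index (which
  # is first in `top2` order only if its sd rank is lower)
  fly_state <- if (mrl[1] >= mrl[2]) top2[1] else top2[2]
  leap_state <- setdiff(top2, fly_state)
  map <- character(model$K)
  map[ord[1:2]] <- "rest"
  map[ord[3]] <- "sing"
  map[fly_state] <- "fly"
  map[leap_state] <- "leap"
  names(map) <- as.character(seq_len(model$K))
  map
}

#' Subsample a 25 Hz state sequence to 1-s behavior labels
#'
#' Maps each decoded state to its behavior and takes, for every second, the
#' modal behavior among that second's samples. Ties are broken by activity
#' precedence `fly > leap > sing > rest` (the more active behavior wins).
#' The target behaviors all unfold over more than a second, so nothing of
#' interest lives below the 1-s grid.
#'
#' @param states Integer state sequence at `rate` Hz (length >= `rate`).
#' @param map State-to-behavior map from [map_states_to_behaviors()].
#' @param t0 GMT epoch seconds of the first sample.
#' @param rate Samples per second (default 25).
#' @return A `behavior_labels` data.frame: `time_s` (start of each second),
#'   `behavior`. A trailing partial second is labeled from its available
#'   samples.
#' @export
subsample_to_1s <- function(states, map, t0 = 0, rate = 25) {
  stopifnot(length(states) >= rate)
  beh <- map[as.character(states)]
  sec <- (seq_along(beh) - 1) %/% rate
  lab <- vapply(split(beh, factor(sec, levels = unique(sec))), modal_behavior, "")
  structure(data.frame(time_s = t0 + unique(sec),
                       behavior = unname(lab)),
            class = c("behavior_labels", "data.frame"))
}

# modal label with activity-precedence tie-break (BEHAVIORS is ordered most
# to least active, so the first maximum in that ordering wins)
modal_behavior <- function(x) {
  counts <- vapply(BEHAVIORS, function(b) sum(x == b), 0L)
  BEHAVIORS[which.max(counts)]
}

#' Extract bouts from a 1-s label sequence
#'
#' Maximal runs of one behavior become bouts; bouts tile the sequence
#' exactly and durations are whole seconds.
#'
#' @param labels A `behavior_labels` data.frame (1-s grid).
#' @param source Provenance tag carried on each bout (`"model"` or
#'   `"audio"`).
#' @return A `bouts` data.frame: `behavior`, `start_s`, `end_s` (GMT epoch;
#'   `end_s` exclusive), `duration_s`, `source`.
#' @export
extract_bouts <- function(labels, source = "model") {
  stopifnot(is.data.frame(labels), all(c("time_s", "behavior") %in% names(labels)))
  if (nrow(labels) == 0)
    return(structure(data.frame(behavior = character(0), start_s = numeric(0),
                                end_s = numeric(0), duration_s = numeric(0),
                                source = character(0)),
                     class = c("bouts", "data.frame")))
  r <- rle(labels$behavior)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  step <- if (nrow(labels) > 1) labels$time_s[2] - labels$time_s[1] else 1
  out <- data.frame(behavior = r$values,
                    start_s = labels$time_s[starts],
                    end_s = labels$time_s[ends] + step,
                    source = source)
  out$duration_s <- out$end_s - out$start_s
  out <- out[c("behavior", "start_s", "end_s", "duration_s", "source")]
  structure(out, class = c("bouts", "data.frame"))
}

#' Apply the minimum song-bout duration rule
#'
#' Song bouts shorter than `min_sing_s` are not biologically meaningful and
#' are relabeled as rest (the bird was stationary either way), after which
#' adjacent same-behavior bouts are re-merged so the result is again a tiling
#' of maximal runs. A bout of exactly `min_sing_s` is retained ("at least
#' 10 s"). The operation is idempotent and conserves total labeled time.
#'
#' @param bouts A `bouts` data.frame.
#' @param min_sing_s Minimum retained song-bout duration in seconds
#'   (default 10).
#' @return A `bouts` data.frame.
#' @export
filter_song_bouts <- function(bouts, min_sing_s = 10) {
  stopifnot(inherits(bouts, "bouts") || is.data.frame(bouts))
  if (nrow(bouts) == 0) return(bouts)
  beh <- bouts$behavior
  short <- beh == "sing" & bouts$duration_s < min_sing_s
  beh[short] <- "rest"
  r <- rle(beh)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  out <- data.frame(behavior = r$values,
                    start_s = bouts$start_s[starts],
                    end_s = bouts$end_s[ends],
                    source = bouts$source[starts])
  out$duration_s <- out$end_s - out$start_s
  out <- out[c("behavior", "start_s", "end_s", "duration_s", "source")]
  structure(out, class = c("bouts", "data.frame"))
}

#' Song bouts of a bout table
#'
#' @param bouts A `bouts` data.frame.
#' @return The rows with `behavior == "sing"`.
#' @export
song_bouts <- function(bouts) {
  out <- bouts[bouts$behavior == "sing", , drop = FALSE]
  rownames(out) <- NULL
  out
}
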