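# Two-phase verification sampling: every screen-positive is invited to the
# gold-standard interview; screen-negatives are randomly selected at 1:k, with
# the ratio allowed to change over the enrolment sequence. Design weights are
# frame counts over realized interviewed counts, so consent non-response is
# absorbed into the weight (this is what reproduces printed weights such as
# 906/287 and 9057/258 from a real study frame).

#' Draw the phase-two verification sample
#'
#' All screen-positives are invited; each screen-negative is invited
#' independently with probability `1/k`, where `k` comes from the schedule
#' entry covering her enrolment position (row order). Invitees are then thinned
#' by the `consented` flag to give the interviewed set.
#'
#' @param population cohort data frame (rows in enrolment order).
#' @param schedule data frame with columns `start` (1-based enrolment index
#'   from which the ratio applies) and `k` (a 1:k ratio, `k >= 1`). The first
#'   `start` must be 1. Default: 1:6 throughout.
#' @param seed integer seed.
#' @return `population` with logical columns `invited` and `interviewed` added.
#' @export
draw_sample <- function(population, schedule = data.frame(start = 1, k = 6),
                        seed) {
  if (NROW(population) == 0) stop("population is empty")
  if (!all(c("start", "k") %in% names(schedule)))
    stop("schedule needs columns start and k")
  if (any(schedule$k < 1)) stop("sampling ratios 1:k require k >= 1")
  if (schedule$start[1] != 1 || is.unsorted(schedule$start))
    stop("schedule must start at index 1 and be sorted")
  set.seed(as.integer(seed))
  n <- nrow(population)
  idx <- findInterval(seq_len(n), schedule$start)
  p_inv <- 1 / schedule$k[idx]
  negative <- population$stratum == "negative"
  invited <- !negative | stats::runif(n) < p_inv
  population$invited <- invited
  population$interviewed <- invited & population$consented
  population
}

#' Stratum design weights from realized counts
#'
#' `w_h = N_h / n_h`: the number of screened women in stratum `h` of the
#' sampling frame divided by the number actually interviewed. The
#' Horvitz-Thompson identity `sum_h n_h w_h = sum_h N_h` holds exactly.
#'
#' @param sample cohort data frame with an `interviewed` column, or the
#'   interviewed subset itself (then all rows count as interviewed).
#' @param frame named numeric vector of frame counts per stratum
#'   (`positive`, `negative`); defaults to the stratum totals of `sample`
#'   itself (appropriate when `sample` is the full screened population with
#'   selection flags).
#' @return a `design_weights` data frame: stratum, frame_count,
#'   interviewed_count, weight.
#' @export
compute_weights <- function(sample, frame = NULL) {
  interviewed <- if ("interviewed" %in% names(sample)) sample$interviewed
                 else rep(TRUE, nrow(sample))
  strata <- c("positive", "negative")
  if (is.null(frame)) {
    if (!"interviewed" %in% names(sample))
      stop("frame counts required when sample does not carry the full frame")
    frame <- table(factor(sample$stratum, levels = strata))
  }
  frame <- as.numeric(frame[strata])
  names(frame) <- strata
  n_h <- vapply(strata, function(s)
    sum(interviewed & sample$stratum == s), numeric(1))
  empty <- strata[n_h < 1]
  if (length(empty) > 0)
    stop("no interviewed women in stratum: ", paste(empty, collapse = ", "))
  if (any(frame <= 0) || anyNA(frame)) stop("frame counts must be positive")
  out <- data.frame(stratum = strata, frame_count = frame,
                    interviewed_count = n_h, weight = frame / n_h,
                    row.names = NULL)
  class(out) <- c("design_weights", "data.frame")
  out
}

#' Attach design weights to interviewed records
#'
#' @param records cohort data frame.
#' @param weights a `design_weights` object from [compute_weights()].
#' @return `records` with a `design_weight` column (`NA` for rows not
#'   interviewed, when an `interviewed` column is present).
#' @export
apply_design_weights <- function(records, weights) {
  w <- weights$weight[match(records$stratum, weights$stratum)]
  if ("interviewed" %in% names(records)) w[!records$interviewed] <- NA_real_
  records$design_weight <- w
  records
}

#' @export
print.design_weights <- function(x, ...) {
  cat("<design_weights> w_h = N_h / n_h\n")
  print.data.frame(x, ...)
  invisible(x)
}
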