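#' Therapy schedules: piecewise-constant dose functions
#'
#' A schedule holds non-overlapping half-open dose windows `[start, end)` for
#' the chemotherapy dose `m(t)` and the targeted-drug dose `n(t)`; both are 0
#' outside their windows. The half-open convention makes the sorted union of
#' window edges (the breakpoints) partition time unambiguously, which is what
#' the segmented integrator consumes.
#'
#' @param chemo Data frame with columns `start`, `end`, `dose` for `m(t)`
#'   (may have zero rows).
#' @param targeted Same layout for `n(t)`.
#' @return An object of class `therapy_schedule` with elements `chemo`,
#'   `targeted` and `breakpoints`.
#' @seealso [continuous_chemo()], [intermittent_chemo()], [targeted_regimen()]
#' @examples
#' therapy_schedule(dose_windows(200, 800, 1))
#' @export
therapy_schedule <- function(chemo = dose_windows(), targeted = dose_windows()) {
  chemo <- validate_windows(chemo, "chemo")
  targeted <- validate_windows(targeted, "targeted")
  bp <- sort(unique(c(chemo$start, chemo$end, targeted$start, targeted$end)))
  structure(list(chemo = chemo, targeted = targeted, breakpoints = bp),
            class = "therapy_schedule")
}

#' Construct a table of dose windows
#'
#' @param start,end Window edges (each window is `[start, end)`).
#' @param dose Nonnegative dose level per window.
#' @return A data frame with columns `start`, `end`, `dose`.
#' @export
dose_windows <- function(start = numeric(), end = numeric(), dose = numeric()) {
  data.frame(start = as.numeric(start), end = as.numeric(end),
             dose = as.numeric(dose))
}

validate_windows <- function(w, what) {
  if (!is.data.frame(w) || !all(c("start", "end", "dose") %in% names(w)))
    stop(what, " windows must have columns start, end, dose", call. = FALSE)
  w <- w[order(w$start), , drop = FALSE]
  rownames(w) <- NULL
  if (nrow(w) == 0L) return(w)
  if (any(!is.finite(as.matrix(w))))
    stop(what, " windows must be finite", call. = FALSE)
  if (any(w$end <= w$start))
    stop(what, " windows must satisfy start < end", call. = FALSE)
  if (any(w$dose < 0))
    stop(what, " doses must be nonnegative", call. = FALSE)
  if (nrow(w) > 1L && any(w$start[-1L] < w$end[-nrow(w)]))
    stop(what, " windows must not overlap", call. = FALSE)
  w
}

#' Evaluate a schedule at a time point
#'
#' Windows are half-open: at `start` the window's dose applies; at `end` the
#' next regime applies.
#'
#' @param schedule A [therapy_schedule()].
#' @param t Time (scalar).
#' @return Named numeric `c(m, n)`.
#' @examples
#' dose_at(continuous_chemo(1), 500)
#' @export
dose_at <- function(schedule, t) {
  eval_w <- function(w) {
    hit <- w$start <= t & t < w$end
    if (any(hit)) w$dose[which(hit)[1L]] else 0
  }
  c(m = eval_w(schedule$chemo), n = eval_w(schedule$targeted))
}

#' @export
print.therapy_schedule <- function(x, ...) {
  cat("therapy schedule (half-open windows)\n")
  show <- function(w, lab) {
    if (nrow(w) == 0L) cat(" ", lab, ": none\n")
    else for (i in seq_len(nrow(w)))
      cat(sprintf("  %s: [%g, %g) dose %g\n", lab, w$start[i], w$end[i],
                  w$dose[i]))
  }
  show(x$chemo, "chemo m")
  show(x$targeted, "targeted n")
  invisible(x)
}

#' Continuous chemotherapy regimen
#'
#' One chemotherapy window at a constant dose, by default over `[200, 800)`
#' (the treatment interval used by every scenario in the battery); no
#' targeted drug.
#'
#' @param m_level Chemotherapy dose (nonnegative).
#' @param start,end Window edges.
#' @return A [therapy_schedule()].
#' @examples
#' s <- continuous_chemo(1)
#' dose_at(s, 500)["m"] # 1
#' dose_at(s, 900)["m"] # 0
#' @export
continuous_chemo <- function(m_level = 1, start = 200, end = 800) {
  if (m_level < 0) stop("'m_level' must be nonnegative", call. = FALSE)
  if (m_level == 0) return(therapy_schedule())
  therapy_schedule(chemo = dose_windows(start, end, m_level))
}

#' Intermittent chemotherapy regimen
#'
#' Therapy switched on and off every 100 time units. The first ON window
#' opens at the usual therapy start (t = 200) and alternation runs to the
#' 800 horizon, giving ON windows `[200, 300)`, `[400, 500)`, `[600, 700)`;
#' the phase and period can be overridden.
#'
#' @param m_level Chemotherapy dose.
#' @param start First ON time.
#' @param end Alternation horizon.
#' @param period ON (and OFF) block length.
#' @return A [therapy_schedule()].
#' @examples
#' s <- intermittent_chemo(1)
#' dose_at(s, 250)["m"] # 1
#' dose_at(s, 350)["m"] # 0
#' @export
intermittent_chemo <- function(m_level = 1, start = 200, end = 800,
                               period = 100) {
  if (m_level < 0) stop("'m_level' must be nonnegative", call. = FALSE)
  if (m_level == 0) return(therapy_schedule())
  n_on <- ceiling((end - start) / (2 * period))
  on_starts <- start + (seq_len(n_on) - 1L) * 2 * period
  w <- dose_windows(on_starts, pmin(on_starts + period, end),
                    rep(m_level, length(on_starts)))
  therapy_schedule(chemo = w)
}

#' Add a PACC-targeted drug window to a schedule
#'
#' Places a single targeted-drug window relative to a chemotherapy course
#' starting at t = 200: `"before"` is `[150, 200)`, `"during"` is
#' `[200, 250)`, `"after"` is `[250, 300)`.
#'
#' @param timing `"before"`, `"during"` or `"after"`.
#' @param n_level Targeted-drug dose (default 0.8).
#' @param base Schedule to extend (default: continuous chemotherapy at
#'   full dose).
#' @return A [therapy_schedule()].
#' @examples
#' s <- targeted_regimen("during")
#' dose_at(s, 225)["n"] # 0.8
#' dose_at(s, 275)["n"] # 0
#' @export
targeted_regimen <- function(timing = c("before", "during", "after"),
                             n_level = 0.8, base = continuous_chemo(1)) {
  timing <- match.arg(timing)
  if (n_level < 0) stop("'n_level' must be nonnegative", call. = FALSE)
  if (n_level == 0) return(base)
  win <- switch(timing, before = c(150, 200), during = c(200, 250),
                after = c(250, 300))
  therapy_schedule(chemo = base$chemo,
                   targeted = dose_windows(win[1L], win[2L], n_level))
}

schedule_to_spec <- function(schedule) {
  list(chemo = unname(split(schedule$chemo, seq_len(nrow(schedule$chemo)))),
       targeted = unname(split(schedule$targeted,
                               seq_len(nrow(schedule$targeted)))))
}

spec_to_schedule <- function(spec) {
  as_windows <- function(rows) {
    if (is.null(rows) || length(rows) == 0L) return(dose_windows())
    do.call(rbind, lapply(rows, function(r)
      dose_windows(r$start, r$end, r$dose)))
  }
  therapy_schedule(chemo = as_windows(spec$chemo),
                   targeted = as_windows(spec$targeted))
}
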