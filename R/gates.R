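#' Rule-based event gating
#'
#' Replaces manual gating with explicit, reproducible threshold rules.  All
#' comparisons are strict, matching the usual quoted conventions (e.g. a
#' CD45 gate "> 0.5" keeps only events strictly above 0.5).
#'
#' Rules:
#' * `channel_above` — keep events with `value > threshold`.
#' * `channel_below` / `viability_below` — keep events with
#'   `value < threshold` (a viability dye marks dead cells high).
#' * `not_doublet` — ratio gate on a height/area channel pair: keeps events
#'   with `height / area > threshold`.  When no height channel is supplied
#'   the gate is a no-op and a warning is raised, since coincidence events
#'   cannot be identified without the pulse-shape channels.
#'
#' @param t a transformed [event_table()].
#' @param rule one of `"viability_below"`, `"channel_above"`,
#'   `"channel_below"`, `"not_doublet"`.
#' @param channel channel the rule applies to (the area channel for
#'   `not_doublet`).
#' @param threshold scalar threshold.
#' @param height_channel pulse-height channel for `not_doublet`.
#' @return list with `table` (gated `event_table`, event order preserved) and
#'   `report` (a `gate_report`: rule, events in/out, threshold).
#' @export
gate_events <- function(t, rule, channel, threshold, height_channel = NULL) {
  stopifnot_event_table(t)
  if (t$transform_state == "raw") stop("gate_events expects a transformed table")
  rule <- match.arg(rule, c("viability_below", "channel_above",
                            "channel_below", "not_doublet"))
  if (!channel %in% t$channels) stop("unknown channel: ", channel)
  n_in <- n_events(t)
  keep <- switch(rule,
    channel_above = t$values[, channel] > threshold,
    channel_below = ,
    viability_below = t$values[, channel] < threshold,
    not_doublet = {
      if (is.null(height_channel) || !height_channel %in% t$channels) {
        warning("no pulse-height channel available; doublet gate is a no-op")
        rep(TRUE, n_in)
      } else {
        t$values[, height_channel] / t$values[, channel] > threshold
      }
    })
  t$values <- t$values[keep, , drop = FALSE]
  if (!is.null(t$provenance)) t$provenance <- t$provenance[keep]
  report <- structure(list(rule = rule, channel = channel,
                           threshold = threshold,
                           events_in = n_in, events_out = sum(keep)),
                      class = "gate_report")
  list(table = t, report = report)
}

#' @export
print.gate_report <- function(x, ...) {
  cat(sprintf("gate '%s' on %s @ %g: %d -> %d events (%d removed)\n",
              x$rule, x$channel, x$threshold, x$events_in, x$events_out,
              x$events_in - x$events_out))
  invisible(x)
}

#' Append gate reports to a JSON-lines audit log
#'
#' @param report a `gate_report` (from [gate_events()]).
#' @param path file to append to.
#' @export
append_gate_log <- function(report, path) {
  line <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
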