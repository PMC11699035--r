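#' Construct an event table
#'
#' The basic cytometry container: an events-by-channels numeric matrix plus
#' the transform state of its values.  Channels are the matrix column names
#' and must be unique.  Fresh tables are on the raw instrument scale
#' (`transform_state = "raw"`); [arcsinh_transform()] and
#' [auto_logicle_transform()] move them to a transformed scale and record the
#' parameters used so the transform can be inverted.
#'
#' @param values numeric matrix, events in rows, channels in columns (column
#'   names are the channel names).
#' @param sample_id sample identifier.
#' @param transform_state one of `"raw"`, `"logicle"`, `"arcsinh"`.
#' @param transform_params per-channel parameter list; must be `NULL` exactly
#'   when `transform_state` is `"raw"`.
#' @param stained logical; `FALSE` marks an unstained control.
#' @return an object of class `event_table`.
#' @export
event_table <- function(values, sample_id, transform_state = "raw",
                        transform_params = NULL, stained = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  ch <- colnames(values)
  if (is.null(ch) || any(!nzchar(ch)))
    stop("values must have channel names as column names")
  if (anyDuplicated(ch))
    stop("duplicate channel names: ", paste(unique(ch[duplicated(ch)]), collapse = ", "))
  transform_state <- match.arg(transform_state, c("raw", "logicle", "arcsinh"))
  if (transform_state == "raw" && !is.null(transform_params))
    stop("raw tables must not carry transform parameters")
  if (transform_state != "raw") {
    if (is.null(transform_params))
      stop("transformed tables must carry transform parameters")
    if (anyNA(values))
      stop("transformed tables must not contain missing values")
  }
  structure(
    list(sample_id = as.character(sample_id),
         channels = ch,
         values = values,
         transform_state = transform_state,
         transform_params = transform_params,
         stained = isTRUE(stained)),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table '%s': %d events x %d channels [%s%s]\n",
              x$sample_id, nrow(x$values), length(x$channels),
              x$transform_state, if (x$stained) "" else ", unstained"))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$values)

n_events <- function(t) nrow(t$values)

stopifnot_event_table <- function(t) {
  if (!inherits(t, "event_table")) stop("expected an event_table")
  invisible(t)
}

#' Merge event tables across samples
#'
#' Row-concatenates tables with identical panels and transform states,
#' keeping per-event sample provenance so composition can later be computed
#' per sample.
#'
#' @param tables list of [event_table()] objects.
#' @return an `event_table` whose `sample_id` is `"merged"` and which carries
#'   a `provenance` element: one sample id per event, in row order.
#' @export
merge_samples <- function(tables) {
  if (!length(tables)) stop("no tables to merge")
  lapply(tables, stopifnot_event_table)
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$channels, ref$channels))
      stop("panel mismatch between samples '", ref$sample_id, "' and '", t$sample_id, "'")
    if (!identical(t$transform_state, ref$transform_state))
      stop("transform state mismatch between samples '", ref$sample_id,
           "' and '", t$sample_id, "'")
  }
  out <- event_table(do.call(rbind, lapply(tables, function(t) t$values)),
                     sample_id = "merged",
                     transform_state = ref$transform_state,
                     transform_params = ref$transform_params,
                     stained = ref$stained)
  out$provenance <- rep(vapply(tables, function(t) t$sample_id, character(1)),
                        vapply(tables, n_events, integer(1)))
  out
}

#' Cap the number of events in a sample
#'
#' Uniform subsampling without replacement down to `cap` events, mirroring
#' the per-sample event caps used when pooling large mass-cytometry cohorts.
#' Tables at or under the cap are returned unchanged.
#'
#' @param t an [event_table()].
#' @param cap maximum number of events to keep (positive integer).
#' @param seed integer seed for the subsample.
#' @return an `event_table` with at most `cap` events (original row order
#'   preserved among survivors).
#' @export
cap_events <- function(t, cap, seed = 0L) {
  stopifnot_event_table(t)
  if (length(cap) != 1L || cap < 1L) stop("cap must be a positive integer")
  n <- n_events(t)
  if (n <= cap) return(t)
  keep <- sort(with_seed(seed, sample.int(n, cap)))
  t$values <- t$values[keep, , drop = FALSE]
  if (!is.null(t$provenance)) t$provenance <- t$provenance[keep]
  t
}
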