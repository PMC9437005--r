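#' Centre-of-mass trace container
#'
#' @param t sample times (us), strictly increasing.
#' @param z axial coordinate (Å).
#' @param probe optional probe/protein label.
#' @return Object of class `trace_series` (a data frame).
#' @export
trace_series <- function(t, z, probe = NA_character_) {
  stopifnot(length(t) == length(z), all(diff(t) > 0), all(is.finite(z)))
  out <- data.frame(t = t, z = z)
  attr(out, "probe") <- probe
  class(out) <- c("trace_series", "data.frame")
  out
}

#' Read a trace from a TSV file with columns t, z
#' @param path input path.
#' @export
read_trace_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  trace_series(df$t, df$z)
}

# All interpolated crossings of the two boundaries +/-b, in time order.
# Columns: t, boundary (+1 for +b, -1 for -b), inward (TRUE when the step
# moves from outside the NPC volume towards the midplane).  Samples landing
# exactly on a boundary are handled by pairing the surrounding samples with
# a nonzero offset: the crossing is timed at the first exact-touch sample.
.boundary_crossings <- function(trace, b) {
  t <- trace$t; z <- trace$z
  out <- list()
  for (s in c(-1, 1)) {
    c0 <- s * b
    dz <- z - c0
    nz <- which(dz != 0)
    if (length(nz) < 2) next
    sgn <- dz[nz]
    k <- which(sgn[-length(sgn)] * sgn[-1] < 0)
    if (!length(k)) next
    i <- nz[k]; j <- nz[k + 1]
    tc <- ifelse(j == i + 1,
                 t[i] + (c0 - z[i]) / (z[j] - z[i]) * (t[j] - t[i]),
                 t[i + 1])           # exact-touch sample(s) in between
    inward <- if (s > 0) z[j] < z[i] else z[j] > z[i]
    out[[length(out) + 1]] <- data.frame(t = tc, boundary = s, inward = inward)
  }
  if (!length(out)) return(data.frame(t = numeric(0), boundary = numeric(0),
                                      inward = logical(0)))
  cr <- do.call(rbind, out)
  cr[order(cr$t), , drop = FALSE]
}

#' First-passage events of a telegraph trace
#'
#' A first passage runs from the moment the trace first enters the NPC
#' volume (`|z| < boundary`) to the moment it exits on the opposite side.
#' Same-side excursions back out of the volume do not reset the clock; an
#' opposite-side exit completes the event and arms the next one.  Events
#' truncated by the ends of the trace are discarded.  Boundary crossing
#' times are located by linear interpolation between samples.
#'
#' @param trace a [trace_series()].
#' @param boundary NPC volume half-width (Å); the pore spans `|z| < 200`.
#' @return List with `events` (data frame `t_enter`, `t_exit`, `duration`,
#'   `direction`), `mfpt`, `sem` and `n`.  With no completed passage the
#'   event table is empty and `mfpt` is `NA`.
#' @export
detect_first_passages <- function(trace, boundary = 200) {
  cr <- .boundary_crossings(trace, boundary)
  ev <- list()
  pending_t <- NA_real_; pending_side <- 0
  for (i in seq_len(nrow(cr))) {
    if (cr$inward[i]) {
      if (pending_side == 0) { pending_t <- cr$t[i]; pending_side <- cr$boundary[i] }
    } else if (pending_side != 0 && cr$boundary[i] == -pending_side) {
      ev[[length(ev) + 1]] <- data.frame(
        t_enter = pending_t, t_exit = cr$t[i],
        duration = cr$t[i] - pending_t,
        direction = -pending_side)      # entered at -side, exited at +(-side)... sign of travel
      pending_side <- 0; pending_t <- NA_real_
    }
    # outward on the same side: clock keeps running
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(t_enter = numeric(0), t_exit = numeric(0),
                            duration = numeric(0), direction = numeric(0))
  n <- nrow(events)
  list(events = events,
       mfpt = if (n) mean(events$duration) else NA_real_,
       sem = if (n > 1) sd(events$duration) / sqrt(n) else NA_real_,
       n = n)
}

#' Crossing events of a telegraph trace
#'
#' A crossing time runs from the moment the trace exits the NPC volume at
#' one boundary back to the *last prior* moment it crossed the opposite
#' boundary, excluding the time spent meandering on the entrance side after
#' first touching its boundary.  Every crossing is contained in exactly one
#' first-passage event and is never longer than it.
#'
#' @inheritParams detect_first_passages
#' @return List with `events` (data frame `t_enter`, `t_exit`, `duration`,
#'   `direction`), `mean_crossing_time`, `sem` and `n`.
#' @export
detect_crossings <- function(trace, boundary = 200) {
  cr <- .boundary_crossings(trace, boundary)
  fp <- detect_first_passages(trace, boundary)$events
  ev <- list()
  for (i in seq_len(nrow(fp))) {
    exit_t <- fp$t_exit[i]
    entry_side <- -fp$direction[i]
    prior <- cr$t[cr$boundary == entry_side & cr$t <= exit_t &
                  cr$t >= fp$t_enter[i]]
    if (!length(prior)) next
    t_last <- max(prior)
    ev[[length(ev) + 1]] <- data.frame(
      t_enter = t_last, t_exit = exit_t, duration = exit_t - t_last,
      direction = fp$direction[i])
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(t_enter = numeric(0), t_exit = numeric(0),
                            duration = numeric(0), direction = numeric(0))
  n <- nrow(events)
  list(events = events,
       mean_crossing_time = if (n) mean(events$duration) else NA_real_,
       sem = if (n > 1) sd(events$duration) / sqrt(n) else NA_real_,
       n = n)
}

#' Normalised crossing-time histogram
#'
#' Histogram construction used for crossing-time distributions: evenly
#' spaced bins over a fixed range (default 15 bins from 0 to 30 us),
#' normalised to unit area over the range; durations outside the range are
#' dropped.
#'
#' @param durations event durations (us).
#' @param bins number of bins.
#' @param range histogram range (us).
#' @return Data frame `t` (bin centres), `count`, `density`.
#' @export
crossing_time_histogram <- function(durations, bins = 15, range = c(0, 30)) {
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  keep <- durations >= range[1] & durations <= range[2]
  idx <- pmin(findInterval(durations[keep], breaks, rightmost.closed = TRUE),
              bins)
  cnt <- .weighted_tabulate(idx, rep(1, sum(keep)), bins)
  width <- diff(breaks)[1]
  data.frame(t = breaks[-1] - width / 2, count = cnt,
             density = if (sum(cnt)) cnt / (sum(cnt) * width) else cnt)
}
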