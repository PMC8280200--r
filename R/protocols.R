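#' Piecewise-constant lighting protocols
#'
#' A \code{light_protocol} is an ordered set of half-open segments
#' \code{[start, end)} with binary light levels that tile
#' \code{[0, total_duration)}.  Switch instants belong to the new segment
#' (right-continuity), so sampling exactly at a dark-to-light transition
#' reads the light level.
#'
#' @param segments data.frame with columns \code{start}, \code{end},
#'   \code{level}; segments must be contiguous from 0 and levels in {0, 1}.
#' @return object of class \code{light_protocol} with fields
#'   \code{segments} and \code{total_duration} (hours).
#' @examples
#' ld_cycle(12, 12, 3)
#' @export
light_protocol <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "level") %in% names(segments)))
  segments <- segments[, c("start", "end", "level")]
  if (nrow(segments) == 0L) {
    return(structure(list(segments = segments, total_duration = 0),
                     class = "light_protocol"))
  }
  if (!all(segments$level %in% c(0, 1)))
    stop("light levels must be 0 or 1")
  if (segments$start[1] != 0)
    stop("protocol must start at t = 0")
  if (any(segments$end <= segments$start))
    stop("segments must have positive duration")
  if (nrow(segments) > 1L &&
      any(abs(segments$start[-1] - segments$end[-nrow(segments)]) > 1e-9))
    stop("segments must tile [0, total_duration) without gaps or overlaps")
  # merge runs of equal level into a canonical form
  keep <- c(TRUE, segments$level[-1] != segments$level[-nrow(segments)])
  if (!all(keep)) {
    grp <- cumsum(keep)
    segments <- data.frame(
      start = tapply(segments$start, grp, min),
      end = tapply(segments$end, grp, max),
      level = segments$level[keep], row.names = NULL)
  }
  rownames(segments) <- NULL
  structure(list(segments = segments,
                 total_duration = segments$end[nrow(segments)]),
            class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  cat(sprintf("Lighting protocol: %d segment(s), %.6g h total\n",
              nrow(x$segments), x$total_duration))
  if (nrow(x$segments) > 0) {
    n <- min(nrow(x$segments), 8L)
    for (k in seq_len(n))
      cat(sprintf("  [%8.6g, %8.6g) %s\n", x$segments$start[k],
                  x$segments$end[k],
                  if (x$segments$level[k] == 1) "light" else "dark"))
    if (nrow(x$segments) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Alternating light:dark cycles
#'
#' Builds \code{n_cycles} repetitions of a light:dark cycle with period
#' \code{T = light_h + dark_h}.  By default each cycle starts with the dark
#' phase, matching recordings that begin at lights-off.
#'
#' @param light_h,dark_h hours of light and dark per cycle (> 0).
#' @param n_cycles number of cycles (>= 1).
#' @param lights_on_first if \code{TRUE}, each cycle starts with light.
#' @return a \code{\link{light_protocol}}.
#' @examples
#' ld_cycle(15, 15, 2)  # 30-h cycles
#' @export
ld_cycle <- function(light_h, dark_h, n_cycles, lights_on_first = FALSE) {
  if (light_h <= 0 || dark_h <= 0) stop("phase durations must be > 0")
  if (n_cycles < 1) stop("'n_cycles' must be >= 1")
  period <- light_h + dark_h
  first_len <- if (lights_on_first) light_h else dark_h
  starts <- as.vector(vapply(seq_len(n_cycles) - 1L, function(k)
    c(k * period, k * period + first_len), numeric(2)))
  lens <- rep(if (lights_on_first) c(light_h, dark_h) else c(dark_h, light_h),
              n_cycles)
  levels <- rep(if (lights_on_first) c(1, 0) else c(0, 1), n_cycles)
  light_protocol(data.frame(start = starts, end = starts + lens,
                            level = levels))
}

#' Constant light or darkness
#'
#' @param level 0 (darkness) or 1 (light).
#' @param duration hours (> 0).
#' @return a \code{\link{light_protocol}} with a single segment.
#' @export
constant_protocol <- function(level, duration) {
  if (!level %in% c(0, 1)) stop("'level' must be 0 or 1")
  if (duration <= 0) stop("'duration' must be > 0")
  light_protocol(data.frame(start = 0, end = duration, level = level))
}

#' Concatenate lighting protocols in time
#'
#' Appends the segments of each subsequent protocol after the previous one;
#' total duration is additive and the operation is associative.
#'
#' @param ... \code{\link{light_protocol}} objects.
#' @return a \code{\link{light_protocol}}.
#' @export
concat_protocols <- function(...) {
  ps <- list(...)
  stopifnot(all(vapply(ps, inherits, logical(1), "light_protocol")))
  offset <- 0
  segs <- list()
  for (p in ps) {
    s <- p$segments
    if (nrow(s) > 0) {
      s$start <- s$start + offset
      s$end <- s$end + offset
      segs[[length(segs) + 1L]] <- s
    }
    offset <- offset + p$total_duration
  }
  if (length(segs) == 0L)
    return(light_protocol(data.frame(start = numeric(), end = numeric(),
                                     level = numeric())))
  light_protocol(do.call(rbind, segs))
}

#' @export
c.light_protocol <- function(...) concat_protocols(...)

#' Superimpose a light pulse on a protocol
#'
#' Forces the light level to 1 on \code{[pulse_start, pulse_start +
#' pulse_duration)}; applying a pulse inside an already-light interval leaves
#' the light function unchanged pointwise.
#'
#' @param base a \code{\link{light_protocol}}.
#' @param pulse_start,pulse_duration hours; the pulse must lie within the
#'   protocol.
#' @return a \code{\link{light_protocol}}.
#' @export
with_pulse <- function(base, pulse_start, pulse_duration) {
  stopifnot(inherits(base, "light_protocol"))
  p0 <- pulse_start; p1 <- pulse_start + pulse_duration
  if (p0 < 0 || p1 > base$total_duration || pulse_duration <= 0)
    stop("pulse [", p0, ", ", p1, ") outside protocol [0, ",
         base$total_duration, ")")
  cuts <- sort(unique(c(base$segments$start, base$segments$end, p0, p1)))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  mid <- (starts + ends) / 2
  lev <- light_value(base, mid)
  lev[starts >= p0 - 1e-12 & ends <= p1 + 1e-12] <- 1
  light_protocol(data.frame(start = starts, end = ends, level = lev))
}

#' Light level at given times
#'
#' Right-continuous lookup of the binary light level.  Times beyond the
#' protocol's duration return the final segment's level (hold) with a
#' warning; negative times are an error.
#'
#' @param protocol a \code{\link{light_protocol}}.
#' @param t time(s) in hours, >= 0.
#' @return numeric vector of 0/1 levels.
#' @export
light_value <- function(protocol, t) {
  stopifnot(inherits(protocol, "light_protocol"))
  if (any(t < 0)) stop("negative time")
  s <- protocol$segments
  if (nrow(s) == 0L) stop("empty protocol has no light level")
  if (any(t >= protocol$total_duration + 1e-9))
    warning("time(s) beyond protocol duration; holding last light level")
  idx <- findInterval(t, s$start)
  idx[idx < 1L] <- 1L
  s$level[idx]
}

# Internal: segment matrix (start, end, level) for the compiled integrators.
protocol_matrix <- function(protocol) {
  s <- protocol$segments
  if (nrow(s) == 0L) s <- data.frame(start = 0, end = Inf, level = 0)
  as.matrix(s)
}

#' Read or write a protocol as JSON
#'
#' The JSON form is either a raw segment list
#' \code{{"segments": [{"start": 0, "end": 144, "level": 0}, ...]}} or the
#' shortcut \code{{"type": "ld", "light_h": 12, "dark_h": 12, "cycles": 3,
#' "lights_on_first": false}} / \code{{"type": "constant", "level": 0,
#' "duration": 144}}.
#'
#' @param path file path.
#' @param protocol a \code{\link{light_protocol}} (for writing).
#' @return \code{read_protocol} returns a \code{\link{light_protocol}};
#'   \code{write_protocol} returns \code{path} invisibly.
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$type)) {
    switch(tolower(x$type),
      ld = ld_cycle(x$light_h, x$dark_h, x$cycles,
                    lights_on_first = isTRUE(x$lights_on_first)),
      constant = constant_protocol(x$level, x$duration),
      stop("unknown protocol type: ", x$type))
  } else if (!is.null(x$segments)) {
    light_protocol(as.data.frame(x$segments))
  } else stop("protocol JSON needs 'segments' or 'type': ", path)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "light_protocol"))
  jsonlite::write_json(list(segments = protocol$segments), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
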