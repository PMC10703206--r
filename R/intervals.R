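#' Closed date intervals on whole calendar days
#'
#' All exposure algebra in pipcox works on sets of closed intervals
#' `[start, end]` of whole calendar days. Two intervals "touch" when the
#' second starts exactly one day after the first ends; touching or
#' overlapping intervals describe one uninterrupted run of days and are
#' merged by [merge_intervals()]. An interval set in *canonical form* is
#' sorted, pairwise disjoint and non-touching, so it is the unique minimal
#' representation of its day set.
#'
#' @param start,end vectors coercible to `Date`; `start <= end` elementwise.
#' @return A data.frame with `Date` columns `start` and `end`.
#' @examples
#' interval_set("2010-01-01", "2010-01-10")
#' @export
interval_set <- function(start = as.Date(character()), end = as.Date(character())) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (length(start) != length(end)) {
    stop("start and end must have the same length")
  }
  if (anyNA(start) || anyNA(end)) stop("interval dates must not be NA")
  if (any(start > end)) stop("interval start must not exceed end")
  data.frame(start = start, end = end)
}

# ---- internal grouped interval algebra on data.table(id, s, e) -------------
# s, e are integer day numbers (inclusive). The grouped variants carry an id
# column so one pass handles a whole cohort; public wrappers use a single id.

iv_empty <- function() {
  data.table(id = character(), s = integer(), e = integer())
}

# Merge overlapping or touching intervals within each id.
# Optional keep_max: carry forward the max of column `v` over merged members.
iv_merge_g <- function(x, keep_max = FALSE) {
  x <- as.data.table(x)
  if (nrow(x) == 0L) {
    if (keep_max) x[, v := numeric(0)]
    return(x)
  }
  x <- x[s <= e]
  setorder(x, id, s, e)
  x[, ce := cummax(e), by = id]
  prev <- x[, shift(ce), by = id]$V1
  x[, g := cumsum(is.na(prev) | s > prev + 1L)]
  if (keep_max) {
    out <- x[, .(id = id[1L], s = s[1L], e = max(e),
                 v = if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)),
             by = g]
  } else {
    out <- x[, .(id = id[1L], s = s[1L], e = max(e)), by = g]
  }
  out[, g := NULL]
  out[]
}

# Day-set intersection of two interval sets, within id.
iv_intersect_g <- function(a, b) {
  a <- iv_merge_g(as.data.table(a)[, .(id, s, e)])
  b <- iv_merge_g(as.data.table(b)[, .(id, s, e)])
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  setkey(b, id, s, e)
  ov <- foverlaps(a, b, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(iv_empty())
  res <- ov[, .(id, s = pmax(s, i.s), e = pmin(e, i.e))]
  iv_merge_g(res)
}

# Day-set difference a \ b, within id.
iv_subtract_g <- function(a, b) {
  a <- iv_merge_g(as.data.table(a)[, .(id, s, e)])
  b <- iv_merge_g(as.data.table(b)[, .(id, s, e)])
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  a[, .arow := .I]
  setkey(b, id, s, e)
  ov <- foverlaps(a, b, type = "any", nomatch = NA)
  keep <- ov[is.na(s), .(id, s = i.s, e = i.e)]
  hit <- ov[!is.na(s)]
  if (nrow(hit)) {
    setorder(hit, .arow, s)
    hit[, bs := pmax(s, i.s)]
    hit[, be := pmin(e, i.e)]
    pieces <- hit[, {
      ps <- c(i.s[1L], be + 1L)
      pe <- c(bs - 1L, i.e[1L])
      ok <- ps <= pe
      list(s = ps[ok], e = pe[ok])
    }, by = .(id, .arow)]
    keep <- rbind(keep, pieces[, .(id, s, e)])
  }
  iv_merge_g(keep)
}

# Clip intervals to per-id bounds given as data.table(id, lo, hi).
iv_clip_g <- function(x, bounds) {
  x <- as.data.table(x)
  if (nrow(x) == 0L) return(x[, .(id, s, e)])
  m <- bounds[x, on = "id", nomatch = NULL]
  m[, s := pmax(s, lo)]
  m[, e := pmin(e, hi)]
  m[s <= e, .(id, s, e)]
}

iv_from_df <- function(x, id = "x") {
  if (is.null(x) || nrow(x) == 0L) return(iv_empty())
  data.table(id = id,
             s = as.integer(as.Date(x$start)),
             e = as.integer(as.Date(x$end)))
}

iv_to_df <- function(x) {
  x <- as.data.table(x)
  setorder(x, s, e)
  data.frame(start = as.Date(x$s, origin = "1970-01-01"),
             end = as.Date(x$e, origin = "1970-01-01"))
}

#' Merge a set of date intervals into canonical form
#'
#' Returns the unique sorted, disjoint, non-touching representation of the
#' union of the input day sets. Intervals that overlap or are exactly
#' adjacent (next start = previous end + 1 day) become one interval with the
#' earliest start and latest end.
#'
#' @param intervals data.frame with `start` and `end` columns (dates).
#' @return data.frame of canonical intervals (possibly zero rows).
#' @examples
#' merge_intervals(interval_set(c("2010-01-01", "2010-01-11", "2010-01-08"),
#'                              c("2010-01-14", "2010-01-31", "2010-01-14")))
#' @export
merge_intervals <- function(intervals) {
  iv_to_df(iv_merge_g(iv_from_df(intervals)))
}

#' Subtract one interval set from another
#'
#' Day-set difference: the days of `a` not covered by `b`, in canonical
#' form. Used to remove proton-pump-inhibitor-protected time from START
#' criterion exposure.
#'
#' @param a,b data.frames with `start`/`end` date columns.
#' @return data.frame of canonical intervals.
#' @export
subtract_intervals <- function(a, b) {
  iv_to_df(iv_subtract_g(iv_from_df(a), iv_from_df(b)))
}

#' Intersect two interval sets
#'
#' Day-set intersection in canonical form. Used for concurrent-medication
#' conditions and for the meds-with-PPI interaction covariate.
#'
#' @param a,b data.frames with `start`/`end` date columns.
#' @return data.frame of canonical intervals.
#' @export
intersect_intervals <- function(a, b) {
  iv_to_df(iv_intersect_g(iv_from_df(a), iv_from_df(b)))
}
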