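# Monthly exposure status from dispensations: days-supply coverage with
# optional carryover of overlapping supplies and a refill-gap allowance.
# Interval t counts as treated when dispensed supply covers at least one
# day of t, or when the uncovered gap since the last covered interval is
# within max_gap_intervals; discontinuation is the first interval beyond
# that allowance.

# vectorized over persons. persons: data.table(person_id, index_date).
# Returns list of matrices: treated (logical n x H), covered, cls (int,
# NA/1=stimulant/2=non_stimulant, gap intervals carry the last class),
# and vectors initiation, discontinuation, switch (interval or NA).
exposure_matrices <- function(persons, dispensations, horizon_months,
                              supply_carryover = TRUE,
                              max_gap_intervals = 1L) {
  n <- nrow(persons)
  H <- horizon_months
  covered <- matrix(FALSE, n, H)
  cls <- matrix(NA_integer_, n, H)
  disp <- data.table::as.data.table(dispensations)
  if (nrow(disp)) {
    if (any(disp$days_supply < 0)) {
      stop_validation("dispensations: negative days_supply")
    }
    disp <- disp[which(disp$drug_class %in% ADHD_CLASSES)]
  }
  if (nrow(disp)) {
    idx <- match(disp$person_id, persons$person_id)
    keep <- which(!is.na(idx))
    disp <- disp[keep]
    d <- data.table::data.table(
      pid = idx[keep],
      day = as.numeric(disp$date - persons$index_date[idx[keep]]),
      cls = match(disp$drug_class, ADHD_CLASSES),
      supply = as.numeric(disp$days_supply)
    )
    data.table::setorder(d, pid, day)
    if (supply_carryover) {
      # e_k = S_k + max_{j<=k} (d_j - S_{j-1}); a_k = max(d_k, e_{k-1})
      d[, `:=`(S = cumsum(supply)), by = pid]
      d[, `:=`(e = S + cummax(day - (S - supply))), by = pid]
      d[, a := pmax(day, data.table::shift(e, fill = -Inf)), by = pid]
    } else {
      d[, `:=`(a = day, e = day + supply)]
    }
    d <- d[e > 0 & a < 30 * H]
    if (nrow(d)) {
      lo <- pmax(0, floor(d$a / 30))
      hi <- pmin(H - 1, floor((d$e - 1) / 30))
      len <- pmax(0L, as.integer(hi - lo + 1L))
      rows <- rep(d$pid, len)
      cls_rep <- rep(d$cls, len)
      tt <- sequence(len, from = as.integer(lo) + 1L) # 1-based interval
      # d is date-ordered, so later dispensations overwrite on overlap
      covered[cbind(rows, tt)] <- TRUE
      cls[cbind(rows, tt)] <- cls_rep
    }
  }

  # a refill gap counts as continuously treated only when coverage
  # resumes within max_gap_intervals; a terminal gap is discontinuation
  # at its first interval
  lc <- matrix(NA_integer_, n, H) # last covered interval at/before t
  nc <- matrix(NA_integer_, n, H) # next covered interval at/after t
  cur <- rep(NA_integer_, n)
  for (t in 0:(H - 1L)) {
    cur <- ifelse(covered[, t + 1L], t, cur)
    lc[, t + 1L] <- cur
  }
  cur <- rep(NA_integer_, n)
  for (t in (H - 1L):0) {
    cur <- ifelse(covered[, t + 1L], t, cur)
    nc[, t + 1L] <- cur
  }
  bridged <- !covered & !is.na(lc) & !is.na(nc) &
    (nc - lc - 1L) <= max_gap_intervals
  treated <- covered | bridged
  initiation <- nc[, 1L] # first covered interval, NA if none
  cls_fill <- cls
  if (H > 1L) {
    for (t in 1:(H - 1L)) {
      carry <- bridged[, t + 1L]
      cls_fill[carry, t + 1L] <- cls_fill[carry, t]
    }
  }
  # discontinuation: first untreated interval at or after initiation
  post <- !treated & !is.na(initiation) &
    (col(treated) - 1L) >= initiation
  discontinuation <- apply_first_true(post)
  # switch: first interval whose (carried) class differs from the class at
  # initiation
  init_cls <- cls[cbind(seq_len(n), pmin(initiation + 1L, H))]
  init_cls[is.na(initiation)] <- NA_integer_
  diff_cls <- !is.na(cls_fill) & !is.na(init_cls) & cls_fill != init_cls
  switch_int <- apply_first_true(diff_cls)
  # day offset of the initiating dispensation (first on/after index)
  init_day <- rep(NA_integer_, n)
  if (exists("d", inherits = FALSE) && nrow(d)) {
    dn <- d[day >= 0, .(day = as.integer(min(day))), by = pid]
    init_day[dn$pid] <- dn$day
  }
  list(treated = treated, covered = covered, cls = cls_fill,
       initiation = initiation, discontinuation = discontinuation,
       switch = switch_int, initiation_day = init_day)
}

# first column index (0-based interval) where a logical matrix row is TRUE
apply_first_true <- function(M) {
  hit <- max.col(M, ties.method = "first")
  has <- M[cbind(seq_len(nrow(M)), hit)]
  out <- ifelse(has, hit - 1L, NA_integer_)
  as.integer(out)
}

#' Derive one person's monthly exposure timeline from dispensations
#'
#' @param dispensations dispensation rows for one person (other persons'
#'   rows are ignored if `person_id` is given).
#' @param index_date the person's index date (time zero).
#' @param horizon_months number of 30-day intervals to classify.
#' @param supply_carryover carry unfinished supply forward across
#'   overlapping dispensations (default `TRUE`).
#' @param max_gap_intervals refill gap (in intervals) still counted as
#'   continuous treatment (default 1).
#' @param person_id optional id to select rows from a larger table.
#' @return object of class `exposure_timeline`: `status` (character vector
#'   over intervals: `untreated`, `treated_initial_drug`,
#'   `treated_other_drug`), `initiation_interval`,
#'   `discontinuation_interval`, `switch_interval` (integer or `NA`).
#' @export
compute_exposure_intervals <- function(dispensations, index_date,
                                       horizon_months = 24L,
                                       supply_carryover = TRUE,
                                       max_gap_intervals = 1L,
                                       person_id = NULL) {
  horizon_months <- check_positive_int(horizon_months, "horizon_months")
  disp <- data.table::as.data.table(dispensations)
  if (!is.null(person_id) && nrow(disp)) {
    disp <- disp[which(disp$person_id == person_id)]
  }
  pid <- if (nrow(disp)) disp$person_id[1L] else 1L
  if (nrow(disp)) disp$person_id <- pid
  persons <- data.table::data.table(person_id = pid,
                                    index_date = as.Date(index_date))
  m <- exposure_matrices(persons, disp, horizon_months,
                         supply_carryover, max_gap_intervals)
  status <- rep("untreated", horizon_months)
  init_cls <- if (!is.na(m$initiation[1L]))
    m$cls[1L, m$initiation[1L] + 1L] else NA_integer_
  tr <- m$treated[1L, ]
  same <- !is.na(m$cls[1L, ]) & !is.na(init_cls) & m$cls[1L, ] == init_cls
  status[tr & same] <- "treated_initial_drug"
  status[tr & !same] <- "treated_other_drug"
  structure(list(
    person_id = pid,
    status = status,
    initiation_interval = m$initiation[1L],
    discontinuation_interval = m$discontinuation[1L],
    switch_interval = m$switch[1L]
  ), class = "exposure_timeline")
}

#' @export
print.exposure_timeline <- function(x, ...) {
  cat("<exposure_timeline>\n")
  cat(sprintf("  initiation: %s, discontinuation: %s, switch: %s\n",
              x$initiation_interval, x$discontinuation_interval,
              x$switch_interval))
  abbrev <- c(untreated = ".", treated_initial_drug = "T",
              treated_other_drug = "S")
  cat(sprintf("  status: %s\n", paste(abbrev[x$status], collapse = "")))
  invisible(x)
}
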