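# Conception-cycle records: validation, IO, and the fertile-window /
# follicular-length coding used throughout the package.

# canonical intercourse column names, fertile-window days -8 .. +3
ic_columns <- function() {
  c(paste0("ic_m", 8:1), "ic_0", paste0("ic_p", 1:3))
}

# canonical CSV header order
cycle_csv_columns <- function() {
  c("woman_id", "cycle_id", "sex", "foll_len", ic_columns(), "study")
}

#' Relative fertile-window days
#'
#' The fertile window spans the 12 days from 8 days before to 3 days after the
#' mucus peak (day 0, the proxy for ovulation).
#'
#' @return Integer vector `-8:3`.
#' @export
fertile_window_days <- function() -8:3

#' Convert a relative fertile-window day to a 1-based day index
#'
#' Day -8 maps to index 1 and day +3 to index 12, so `k = day + 9`.
#'
#' @param day Integer vector of relative days in `-8..3` (0 = mucus peak).
#' @return Integer indices in `1..12`.
#' @seealso [index_to_relative_day()] for the inverse.
#' @export
relative_day_to_index <- function(day) {
  if (!is.numeric(day) || any(is.na(day)) || any(day != round(day))) {
    stop("`day` must be integer-valued and non-missing", call. = FALSE)
  }
  if (any(day < -8 | day > 3)) {
    stop("relative day outside the fertile window -8..3: ",
         paste(day[day < -8 | day > 3], collapse = ", "), call. = FALSE)
  }
  as.integer(day + 9L)
}

#' @rdname relative_day_to_index
#' @param k Integer vector of day indices in `1..12`.
#' @export
index_to_relative_day <- function(k) {
  if (!is.numeric(k) || any(is.na(k)) || any(k != round(k)) ||
      any(k < 1 | k > 12)) {
    stop("`k` must be an integer index in 1..12", call. = FALSE)
  }
  as.integer(k - 9L)
}

#' Categorize follicular-phase length
#'
#' Follicular-phase length (days from the first day of menstruation to the
#' mucus reference day) is coarsened into four ordered classes:
#' class 1 for lengths of at most 13 days, class 2 for 14--16, class 3 for
#' 17--19 and class 4 for 20 days or more.
#'
#' @param w Positive integer vector of follicular-phase lengths in days.
#'   `NA` entries are passed through as `NA`.
#' @return Integer vector of classes in `1..4`.
#' @export
categorize_follicular_length <- function(w) {
  ok <- is.na(w) | (is.numeric(w) & w == round(w) & w >= 1)
  if (!is.numeric(w) || !all(ok)) {
    stop("follicular length must be a positive integer number of days",
         call. = FALSE)
  }
  cls <- rep(NA_integer_, length(w))
  obs <- !is.na(w)
  cls[obs] <- cut(w[obs], breaks = c(0, 13, 16, 19, Inf), labels = FALSE)
  as.integer(cls)
}

# labels matching the published class bins, used in tabulations
follicular_class_labels <- function() c("<=13", "14-16", "17-19", ">19")

#' Construct a validated conception-cycle dataset
#'
#' A `cycle_dataset` is a data frame with one row per conception cycle and
#' columns `woman_id`, `cycle_id`, `sex` (0 = male, 1 = female), `foll_len`
#' (follicular length in days, may be `NA`), `foll_class` (ordinal 1..4,
#' derived from `foll_len`), the twelve intercourse indicators
#' `ic_m8 .. ic_p3` for relative days -8..+3, and `study` (free-text
#' provenance label).
#'
#' Rows violating the record invariants are rejected, collected in the
#' `"rejected"` attribute (row number and reason), and a message reports the
#' count.  Cycles with no intercourse anywhere in the fertile window are
#' rejected: under the model their female-probability is the empty product
#' (identically 1) whatever the parameters, so they carry no information.
#'
#' @param df Data frame with at least `sex` and the 12 intercourse columns;
#'   `woman_id`, `cycle_id`, `foll_len`, `study` are optional.  `sex` accepts
#'   0/1 or M/F (case-insensitive).
#' @return A `cycle_dataset` (also a `data.frame`), with attribute
#'   `"rejected"` describing dropped rows.
#' @export
cycle_dataset <- function(df) {
  if (!is.data.frame(df)) stop("`df` must be a data frame", call. = FALSE)
  icc <- ic_columns()
  missing_cols <- setdiff(c("sex", icc), names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n_in <- nrow(df)
  if (n_in == 0) stop("empty input: no cycle rows", call. = FALSE)

  if (!"woman_id" %in% names(df)) df$woman_id <- sprintf("W%04d", seq_len(n_in))
  if (!"cycle_id" %in% names(df)) df$cycle_id <- sprintf("C%04d", seq_len(n_in))
  if (!"foll_len" %in% names(df)) df$foll_len <- NA_integer_
  if (!"study" %in% names(df))    df$study <- NA_character_

  sex <- parse_sex(df$sex)
  reasons <- character(n_in)
  reasons[is.na(sex)] <- "unparseable sex code"

  ic <- as.matrix(df[icc])
  suppressWarnings(storage.mode(ic) <- "numeric")
  bad_ic <- apply(ic, 1, function(r) any(is.na(r) | !(r %in% c(0, 1))))
  reasons[reasons == "" & bad_ic] <- "intercourse indicator not in {0, 1}"
  none <- !bad_ic & rowSums(ic) == 0
  reasons[reasons == "" & none] <- "no intercourse in the fertile window"

  fl <- suppressWarnings(as.numeric(df$foll_len))
  bad_fl <- !is.na(df$foll_len) & trimws(as.character(df$foll_len)) != "" &
    (is.na(fl) | fl != round(fl) | fl < 1)
  reasons[reasons == "" & bad_fl] <- "invalid follicular length"

  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  if (!any(keep)) {
    stop("no valid cycles after validation (", nrow(rejected),
         " row(s) rejected)", call. = FALSE)
  }
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " cycle row(s) rejected at ingest; see attr(x, \"rejected\")")
  }

  out <- data.frame(
    woman_id = as.character(df$woman_id)[keep],
    cycle_id = as.character(df$cycle_id)[keep],
    sex = sex[keep],
    foll_len = ifelse(is.na(fl[keep]), NA_integer_, as.integer(fl[keep])),
    stringsAsFactors = FALSE
  )
  ic_keep <- matrix(as.integer(ic[keep, , drop = FALSE]), ncol = 12,
                    dimnames = list(NULL, icc))
  out <- cbind(out, as.data.frame(ic_keep))
  out$study <- as.character(df$study)[keep]
  out$foll_class <- categorize_follicular_length(out$foll_len)
  out <- out[c("woman_id", "cycle_id", "sex", "foll_len", "foll_class",
               icc, "study")]
  rownames(out) <- NULL
  structure(out, rejected = rejected,
            class = c("cycle_dataset", "data.frame"))
}

# normalize sex codes: 0/1 and M/F (case-insensitive) -> 0 = male, 1 = female
parse_sex <- function(x) {
  s <- toupper(trimws(as.character(x)))
  out <- rep(NA_integer_, length(s))
  out[s %in% c("0", "M", "MALE")] <- 0L
  out[s %in% c("1", "F", "FEMALE")] <- 1L
  out
}

#' @export
print.cycle_dataset <- function(x, ...) {
  cat("<cycle_dataset> ", nrow(x), " conception cycles (",
      sum(x$sex == 1), " female, ", sum(x$sex == 0), " male)\n", sep = "")
  NextMethod()
}

#' Extract the n x 12 intercourse-indicator matrix
#'
#' @param data A `cycle_dataset`.
#' @return Integer matrix with one row per cycle, columns ordered by relative
#'   day -8..+3.
#' @export
intercourse_matrix <- function(data) {
  stopifnot(inherits(data, "cycle_dataset"))
  as.matrix(data[ic_columns()])
}

#' Read conception cycles from the canonical CSV
#'
#' The canonical file is comma-separated UTF-8 with header
#' `woman_id,cycle_id,sex,foll_len,ic_m8,...,ic_0,...,ic_p3,study`;
#' `foll_len` may be empty.  Rows failing validation are rejected with a
#' per-row report (see [cycle_dataset()]); an empty valid result is an error.
#'
#' @param path Path to the CSV file.
#' @return A validated `cycle_dataset`, ingestion order preserved.
#' @export
read_cycles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(cycle_csv_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$foll_len[trimws(df$foll_len) == ""] <- NA
  cycle_dataset(df)
}

#' Write conception cycles to the canonical CSV
#'
#' @param data A `cycle_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cycles <- function(data, path) {
  stopifnot(inherits(data, "cycle_dataset"))
  out <- as.data.frame(data)[cycle_csv_columns()]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Tabulate intercourse frequency by fertile-window day
#'
#' For each relative day, the number of cycles with an intercourse act on
#' that day and its relative frequency (%) over all cycles, rounded to two
#' decimals.  Counts across days may sum to more than `n` because a cycle can
#' have intercourse on several days.
#'
#' @param data A non-empty `cycle_dataset`.
#' @return Data frame with columns `day`, `count`, `rel_freq`.
#' @export
tabulate_intercourse <- function(data) {
  stopifnot(inherits(data, "cycle_dataset"))
  n <- nrow(data)
  if (n < 1) stop("empty dataset", call. = FALSE)
  counts <- colSums(intercourse_matrix(data))
  data.frame(day = fertile_window_days(),
             count = as.integer(counts),
             rel_freq = round(100 * counts / n, 2),
             row.names = NULL)
}

#' Tabulate the categorized follicular-length distribution
#'
#' Counts partition the dataset, so they sum to `n` and the percentages sum
#' to 100 within rounding.
#'
#' @param data A `cycle_dataset` in which every cycle has a follicular class.
#' @return Data frame with columns `class`, `label`, `count`, `rel_freq`.
#' @export
tabulate_follicular <- function(data) {
  stopifnot(inherits(data, "cycle_dataset"))
  n <- nrow(data)
  if (n < 1) stop("empty dataset", call. = FALSE)
  if (anyNA(data$foll_class)) {
    stop("missing follicular class for cycle(s): ",
         paste(data$cycle_id[is.na(data$foll_class)], collapse = ", "),
         call. = FALSE)
  }
  counts <- tabulate(data$foll_class, nbins = 4)
  data.frame(class = 1:4,
             label = follicular_class_labels(),
             count = as.integer(counts),
             rel_freq = round(100 * counts / n, 2),
             row.names = NULL)
}
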