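parse_flex_date <- function(x) {
  x <- trimws(as.character(x))
  blank <- is.na(x) | x == "" | toupper(x) == "NA"
  out <- rep(as.Date(NA), length(x))
  toks <- strsplit(gsub("/", "-", x), "-", fixed = TRUE)
  for (i in seq_along(x)) {
    if (blank[i]) next
    tk <- toks[[i]]
    if (length(tk) != 3) next
    # ISO when the leading token is a 4-digit year, otherwise the
    # day-month-year dialect with 2- or 4-digit years (e.g. "23-4-97");
    # impossible dates such as "31-2-99" fail strptime -> NA
    fmt <- if (nchar(tk[1]) == 4) "%Y-%m-%d"
           else if (nchar(tk[3]) == 4) "%d-%m-%Y" else "%d-%m-%y"
    out[i] <- as.Date(paste(tk, collapse = "-"), format = fmt)
  }
  failed <- !blank & is.na(out)
  attributes(out) <- list(class = "Date")
  attr(out, "failed") <- failed
  out
}

check_columns <- function(df, needed, path) {
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
}

#' Read turtle and bone tables from CSV
#'
#' Parses the two standard input tables.  Dates are accepted in ISO 8601
#' (\code{2000-04-25}) or day-month-year (\code{25-4-00}) form.  Row-level
#' problems (unparseable dates, non-numeric measurements) are collected
#' with \code{file:line} positions and raised together.
#'
#' @param turtles_path CSV with columns \code{id}, \code{date_tagged},
#'   \code{scl_tagging_cm}, \code{date_otc}, \code{date_stranded},
#'   \code{scl_recovery_cm}, \code{fibropapilloma}.
#' @param bones_path CSV with columns \code{turtle_id}, \code{lag_index},
#'   \code{lag_diameter_mm}, \code{is_double}, \code{section_diameter_mm},
#'   \code{resorption_diameter_mm}, \code{otc_diameter_mm}.
#' @return List with data frames \code{turtles} and \code{bones}.
#' @export
read_turtle_tables <- function(turtles_path, bones_path) {
  errors <- character(0)
  turtles <- utils::read.csv(turtles_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  check_columns(turtles, c("id", "date_tagged", "scl_tagging_cm",
                           "date_otc", "date_stranded", "scl_recovery_cm",
                           "fibropapilloma"), turtles_path)
  num <- function(col, df, path, offset = 1) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
    if (length(bad))
      errors <<- c(errors, sprintf("%s:%d: non-numeric %s ('%s')", path,
                                   bad + offset, col, df[[col]][bad]))
    v
  }
  dat <- function(col, df, path, offset = 1) {
    v <- parse_flex_date(df[[col]])
    bad <- which(attr(v, "failed"))
    if (length(bad))
      errors <<- c(errors, sprintf("%s:%d: unparseable date in %s ('%s')",
                                   path, bad + offset, col, df[[col]][bad]))
    attr(v, "failed") <- NULL
    v
  }
  if (nrow(turtles)) {
    turtles$date_tagged <- dat("date_tagged", turtles, turtles_path)
    turtles$date_otc <- dat("date_otc", turtles, turtles_path)
    turtles$date_stranded <- dat("date_stranded", turtles, turtles_path)
    turtles$scl_tagging_cm <- num("scl_tagging_cm", turtles, turtles_path)
    turtles$scl_recovery_cm <- num("scl_recovery_cm", turtles, turtles_path)
    turtles$fibropapilloma <- toupper(trimws(turtles$fibropapilloma)) %in%
      c("TRUE", "T", "1", "YES")
  } else {
    for (col in c("date_tagged", "date_otc", "date_stranded"))
      turtles[[col]] <- as.Date(character(0))
    for (col in c("scl_tagging_cm", "scl_recovery_cm"))
      turtles[[col]] <- numeric(0)
    turtles$fibropapilloma <- logical(0)
  }

  bones <- utils::read.csv(bones_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  check_columns(bones, c("turtle_id", "lag_index", "lag_diameter_mm",
                         "is_double", "section_diameter_mm",
                         "resorption_diameter_mm", "otc_diameter_mm"),
                bones_path)
  if (nrow(bones)) {
    for (col in c("lag_index", "lag_diameter_mm", "section_diameter_mm",
                  "resorption_diameter_mm", "otc_diameter_mm"))
      bones[[col]] <- num(col, bones, bones_path)
    bones$is_double <- toupper(trimws(bones$is_double)) %in%
      c("TRUE", "T", "1", "YES")
  } else {
    for (col in c("lag_index", "lag_diameter_mm", "section_diameter_mm",
                  "resorption_diameter_mm", "otc_diameter_mm"))
      bones[[col]] <- numeric(0)
    bones$is_double <- logical(0)
  }

  if (length(errors))
    stop(paste(c("input errors:", errors), collapse = "\n  "))
  list(turtles = turtles, bones = bones)
}

#' Write turtle and bone tables to CSV
#'
#' Inverse of \code{\link{read_turtle_tables}}: writes the two standard
#' tables with ISO 8601 dates at full numeric precision, so a write/read
#' round trip is lossless.
#'
#' @param turtles,bones Data frames in the standard schemas.
#' @param turtles_path,bones_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_turtle_tables <- function(turtles, bones, turtles_path, bones_path) {
  t2 <- turtles
  for (col in c("date_tagged", "date_otc", "date_stranded"))
    t2[[col]] <- format(as.Date(t2[[col]]), "%Y-%m-%d")
  utils::write.csv(t2, turtles_path, row.names = FALSE, na = "")
  utils::write.csv(bones, bones_path, row.names = FALSE, na = "")
  invisible(c(turtles_path, bones_path))
}
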