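# The observation model: girth (gbh) is what the field crew records, at
# 0.5 cm resolution; diameter (dbh) is what the database stores, at 0.1 cm.

#' Convert girth at breast height to diameter
#'
#' The field girth is divided by pi and rounded half-up to the database's
#' 0.1 cm resolution. The field threshold of 30 cm gbh corresponds to
#' 9.5 cm dbh.
#'
#' @param girth_cm Non-negative girth(s) in cm.
#' @return Diameter(s) in cm at 0.1 cm resolution.
#' @examples
#' gbh_to_dbh(30)  # 9.5
#' gbh_to_dbh(250) # 79.6
#' @export
gbh_to_dbh <- function(girth_cm) {
  if (any(!is.na(girth_cm) & girth_cm < 0)) {
    psp_stop("girth must be non-negative", "psp_domain_error")
  }
  round_half_up(girth_cm / pi, 0.1)
}

#' Convert diameter to girth at field resolution
#'
#' Inverse of [gbh_to_dbh()], used by the synthetic observation layer:
#' diameter times pi, rounded half-up to the 0.5 cm field resolution.
#'
#' @param dbh_cm Non-negative diameter(s) in cm.
#' @return Girth(s) in cm at 0.5 cm resolution.
#' @examples
#' dbh_to_gbh(9.5) # 30
#' @export
dbh_to_gbh <- function(dbh_cm) {
  if (any(!is.na(dbh_cm) & dbh_cm < 0)) {
    psp_stop("dbh must be non-negative", "psp_domain_error")
  }
  round_half_up(dbh_cm * pi, 0.5)
}

#' Diameter assigned to a 10-cm diameter class
#'
#' Very large trees (girth above 250 cm) were not measured during 1982-1990
#' but binned into 10-cm wide diameter classes. The class midpoint is this
#' package's stored value (unbiased under a uniform within-class
#' distribution).
#'
#' @param lower_cm,upper_cm Class bounds in cm; `upper_cm - lower_cm` must
#'   equal 10.
#' @return Midpoint diameter(s) in cm.
#' @examples
#' class_to_dbh(80, 90) # 85
#' @export
class_to_dbh <- function(lower_cm, upper_cm) {
  if (any(is.na(lower_cm) | is.na(upper_cm)) ||
      any(abs((upper_cm - lower_cm) - 10) > 1e-9) || any(lower_cm < 0)) {
    psp_stop("diameter classes must be well-formed 10-cm wide intervals",
             "psp_domain_error")
  }
  (lower_cm + upper_cm) / 2
}

#' The 10-cm diameter class containing a diameter
#'
#' @param dbh_cm Diameter(s) in cm.
#' @return Tibble with `lower_cm`, `upper_cm` (classes `[k*10, (k+1)*10)`).
#' @export
dbh_to_class <- function(dbh_cm) {
  lower <- floor(dbh_cm / 10) * 10
  tibble::tibble(lower_cm = lower, upper_cm = lower + 10)
}

#' Carry relascope readings forward between measurement years
#'
#' The very largest, extremely irregular trees are measured with the
#' Bitterlich relascope every five years; the value is reported for the
#' intermediate campaigns until the next reading.
#'
#' @param series Tibble with columns `campaign_year`, `dbh_cm`, `method`
#'   (`"relascope"` rows are the readings; intermediate campaigns have
#'   `NA` dbh).
#' @return The series with intermediate campaigns filled with the last
#'   relascope value and `method = "carried_forward"`; campaigns before the
#'   first reading and after the last one are untouched.
#' @export
carry_forward_relascope <- function(series) {
  stopifnot(all(c("campaign_year", "dbh_cm", "method") %in% names(series)))
  s <- dplyr::arrange(series, .data$campaign_year)
  reading <- which(!is.na(s$method) & s$method == "relascope" &
                     !is.na(s$dbh_cm))
  if (length(reading) >= 1) {
    last_reading <- max(reading)
    for (i in seq_len(nrow(s))) {
      if (i > min(reading) && i <= last_reading && is.na(s$dbh_cm[i])) {
        prev <- max(reading[reading < i])
        s$dbh_cm[i] <- s$dbh_cm[prev]
        s$method[i] <- "carried_forward"
      }
    }
    # readings are reported up to the next measurement: also fill past the
    # last reading when later campaigns exist with no value
    after <- which(seq_len(nrow(s)) > last_reading & is.na(s$dbh_cm))
    if (length(after)) {
      s$dbh_cm[after] <- s$dbh_cm[last_reading]
      s$method[after] <- "carried_forward"
    }
  }
  s
}
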