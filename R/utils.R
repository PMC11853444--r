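# Internal helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Timepoint labels are "pre" or non-negative integer days kept as character;
# this maps them to a sortable numeric key ("pre" sorts before day 0).
day_key <- function(day) {
  ifelse(day == "pre", -1, suppressWarnings(as.numeric(day)))
}

stop_cfmrd <- function(msg, class = "cfmrd_error") {
  rlang::abort(msg, class = c(class, "cfmrd_error"))
}

stop_not_evaluable <- function(msg) {
  stop_cfmrd(msg, class = "cfmrd_not_evaluable")
}

#' Map sampling days to the nominal study schedule
#'
#' Post-transplant samples drawn within a window of a scheduled study day
#' (28, 56, 84 by default) are aligned to that nominal day so that series
#' from different assays can be joined. Days tied between two nominal days
#' go to the nearer one; on an exact tie the earlier nominal day wins.
#' Days outside every window are returned unchanged.
#'
#' @param day Integer vector of actual sampling days.
#' @param nominal Scheduled study days.
#' @param window Maximum distance (days) for alignment.
#' @return Integer vector of aligned days.
#' @examples
#' nominal_day(c(25, 42, 90, 120))
#' @export
nominal_day <- function(day, nominal = c(28L, 56L, 84L), window = 14L) {
  nominal <- sort(as.integer(nominal))
  vapply(as.integer(day), function(d) {
    dist <- abs(nominal - d)
    if (min(dist) > window) return(d)
    nominal[which.min(dist)] # which.min takes the first (earlier) on ties
  }, integer(1))
}

round_half_up <- function(x, digits = 0) {
  # Printed clinical tables round halves up; base round() rounds to even.
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
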