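#' Length-zone table for the tape baseline
#'
#' A Broselow-style table mapping contiguous supine-length intervals to a
#' single zone weight. Zones are half-open `[lower, upper)` except the
#' last, which includes its upper bound; the overall domain is the tape
#' range 45.9--146.5 cm. The default table is synthetic: zone weights are
#' derived from the default growth chart at each zone's midpoint length
#' (sex-averaged median weight at the height-equivalent age), which makes
#' them monotone by construction. Real tape values with the same schema
#' can be supplied via [read_zone_table()].
#'
#' @param chart a `growth_chart` used to derive the default zone weights.
#' @param zone_width nominal zone width in cm.
#' @return a `zone_table` data.frame with columns `lower_cm`, `upper_cm`,
#'   `label`, `weight_kg`.
#' @export
zone_table <- function(chart = growth_chart(), zone_width = 4) {
  breaks <- unique(c(seq(45.9, 146.5, by = zone_width), 146.5))
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  w <- vapply(mids, function(m) {
    ws <- vapply(c("male", "female"), function(sx) {
      # lengths below the 1-month median belong to neonates off the grid;
      # clamp to the curve range so the first zones take the youngest weight
      med <- range(chart$height_median_cm[chart$sex == sx])
      a <- height_to_age(chart, sx, min(max(m, med[1]), med[2]))
      chart_params(chart, sx, a)$weight_median
    }, numeric(1))
    round(mean(ws), 1)
  }, numeric(1))
  w <- cummax(w)
  tab <- data.frame(lower_cm = utils::head(breaks, -1),
                    upper_cm = utils::tail(breaks, -1),
                    label = sprintf("Z%02d", seq_along(mids)),
                    weight_kg = w, stringsAsFactors = FALSE)
  new_zone_table(tab)
}

new_zone_table <- function(tab) {
  req <- c("lower_cm", "upper_cm", "label", "weight_kg")
  if (!all(req %in% names(tab)))
    stop("zone table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  tab <- tab[order(tab$lower_cm), req]
  rownames(tab) <- NULL
  if (any(tab$upper_cm <= tab$lower_cm))
    stop("each zone must have upper_cm > lower_cm", call. = FALSE)
  if (nrow(tab) > 1 &&
      any(abs(tab$lower_cm[-1] - tab$upper_cm[-nrow(tab)]) > 1e-9))
    stop("zones must be contiguous and non-overlapping", call. = FALSE)
  if (any(diff(tab$weight_kg) < 0))
    stop("zone weights must be non-decreasing with length", call. = FALSE)
  if (abs(tab$lower_cm[1] - 45.9) > 1e-9 ||
      abs(tab$upper_cm[nrow(tab)] - 146.5) > 1e-9)
    stop("zone table domain must span the tape range [45.9, 146.5] cm",
         call. = FALSE)
  class(tab) <- c("zone_table", "data.frame")
  tab
}

#' Read or write a length-zone table CSV
#'
#' @param path CSV with columns `lower_cm`, `upper_cm`, `label`,
#'   `weight_kg`.
#' @export
read_zone_table <- function(path) {
  new_zone_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                 comment.char = "#"))
}

#' @rdname read_zone_table
#' @param table a `zone_table`.
#' @export
write_zone_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Length-zone weight estimate
#'
#' Looks up the unique zone containing each supine length (binary search
#' over the zone lower bounds) and returns its weight. Lengths outside
#' the tape range [45.9, 146.5] cm raise an error, mirroring the clinical
#' exclusion rule for children off the tape.
#'
#' @param table a `zone_table`.
#' @param length_cm supine length(s) in cm.
#' @return zone weight(s) in kg.
#' @export
bt_estimate <- function(table, length_cm) {
  lo <- table$lower_cm[1]
  hi <- table$upper_cm[nrow(table)]
  bad <- length_cm < lo | length_cm > hi
  if (any(bad))
    stop(sprintf("length %s cm outside the tape range [%.1f, %.1f]",
                 paste(signif(length_cm[bad], 4), collapse = ", "),
                 lo, hi), call. = FALSE)
  idx <- findInterval(length_cm, table$lower_cm)
  idx[length_cm >= hi] <- nrow(table)   # final zone is upper-inclusive
  table$weight_kg[idx]
}
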