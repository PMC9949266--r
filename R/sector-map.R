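# Prostate sector map: zone-labeled sectors used for lesion localization and
# sector-weighted counting.

#' Prostate sector map
#'
#' A sector map assigns every sector identifier to exactly one prostate zone
#' (transition zone `TZ` or peripheral zone `PZ`). Lesions are localized on
#' sectors and their TP/FP/FN contributions are split evenly across the
#' sectors they span.
#'
#' @param sector_ids Character vector of unique sector identifiers.
#' @param zones Character vector of the same length with values `"TZ"`/`"PZ"`.
#' @return Object of class `sector_map`: list with `sector_ids` and `zone_of`
#'   (named character vector sector -> zone).
#' @export
sector_map <- function(sector_ids, zones) {
  sector_ids <- as.character(sector_ids)
  zones <- as.character(zones)
  if (length(sector_ids) != length(zones)) stop("sector_ids/zones length mismatch")
  if (anyDuplicated(sector_ids)) stop("duplicate sector ids")
  if (!all(zones %in% c("TZ", "PZ"))) stop("zones must be 'TZ' or 'PZ'")
  if (!all(c("TZ", "PZ") %in% zones)) stop("each zone needs at least one sector")
  zone_of <- stats::setNames(zones, sector_ids)
  structure(list(sector_ids = sector_ids, zone_of = zone_of),
            class = "sector_map")
}

#' Default 12-sector map
#'
#' A simplified scheme with 6 transition-zone and 6 peripheral-zone sectors
#' (left/right at apex, mid-gland and base). A finer map, up to the full
#' PI-RADS v2.1 sector sheet, can be supplied through [sector_map()]; all
#' downstream statistics depend only on sector-to-zone membership.
#'
#' @return A [sector_map()].
#' @export
default_sector_map <- function() {
  pos <- c("apex", "mid", "base")
  side <- c("L", "R")
  ids <- c(outer(c("TZ", "PZ"), outer(pos, side, paste, sep = "_"),
                 paste, sep = "_"))
  sector_map(ids, substr(ids, 1, 2))
}

#' @export
print.sector_map <- function(x, ...) {
  cat(sprintf("<sector_map> %d sectors (%d TZ, %d PZ)\n",
              length(x$sector_ids), sum(x$zone_of == "TZ"),
              sum(x$zone_of == "PZ")))
  invisible(x)
}

#' Sectors belonging to a zone
#'
#' @param map A [sector_map()].
#' @param zone `"TZ"` or `"PZ"`.
#' @return Character vector of sector ids.
#' @export
zone_sectors <- function(map, zone) {
  stopifnot(inherits(map, "sector_map"))
  zone <- match.arg(zone, c("TZ", "PZ"))
  names(map$zone_of)[map$zone_of == zone]
}

# lesions carry sectors as a ';'-separated string column; these helpers
# convert to/from lists
split_sectors <- function(x) strsplit(as.character(x), ";", fixed = TRUE)
join_sectors <- function(x) vapply(x, paste, character(1L), collapse = ";")
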